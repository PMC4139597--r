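## File formats: FASTA sequences (via seqinr), coarse-grained PDB trace
## files (one pseudo-atom per site; read via bio3d, multi-MODEL trajectory
## writing by fixed-width formatting), YAML run configs and TSV energy logs.

.PDB_ATOM <- list(
  protein = c(anchor = "CA", branch = "SC", mid = "P"),
  nucleic_acid = c(anchor = "S", branch = "B", mid = "P"),
  polysaccharide = c(anchor = "O4", branch = "", mid = "SUG")
)

.RES3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
           Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
.RES3_NA <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "U")
.RES3_SUG <- c(a = "GLA", b = "GLB")

.res3_of <- function(model, code) {
  switch(model, protein = .RES3[code], nucleic_acid = .RES3_NA[code],
         polysaccharide = .RES3_SUG[code])
}

.code_of_res3 <- function(model, res3) {
  tab <- switch(model, protein = .RES3, nucleic_acid = .RES3_NA,
                polysaccharide = .RES3_SUG)
  out <- names(tab)[match(res3, tab)]
  if (anyNA(out))
    stop("unknown residue name(s): ",
         paste(unique(res3[is.na(out)]), collapse = ", "))
  out
}

#' Read chain sequences from a FASTA file
#'
#' One record per chain; the record order defines the chain order (and the
#' chain breaks of a multi-chain topology). Case is preserved, so the
#' polysaccharide alphabet ("a" = alpha-D-glucose, "b" = beta-D-glucose)
#' passes through unchanged.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sq <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           seqtype = "AA")
  if (length(sq) == 0) stop("no FASTA records in ", path)
  vapply(sq, function(s) as.character(s)[1], "")
}

#' Write chain sequences to a FASTA file
#'
#' @param sequences character vector (one string per chain).
#' @param path output file.
#' @param names record names.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequences, path,
                           names = paste0("chain", seq_along(sequences))) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0(">", names[i]), sequences[i]), con)
  }
  invisible(path)
}

## one MODEL's worth of ATOM lines for a conformation
.pdb_atom_lines <- function(topology, conf, serial0 = 0L) {
  model <- topology$model
  an <- .PDB_ATOM[[model]]
  lines <- character(0)
  serial <- serial0
  fmt <- function(name, resno, chain, xyz, res3) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, res3, LETTERS[chain], resno,
            xyz[1], xyz[2], xyz[3])
  }
  A <- conf$anchors
  if (model == "polysaccharide") {
    ds <- derived_sites(topology, conf)
    for (c_i in seq_len(topology$n_chain)) {
      aidx <- which(topology$anchors$chain == c_i)
      ridx <- which(topology$mids$chain == c_i)
      n_units <- length(ridx)
      for (k in seq_along(aidx)) {
        resno <- min(k, n_units)
        code <- topology$mids$code[ridx[resno]]
        lines <- c(lines, fmt(an[["anchor"]], resno, c_i, A[aidx[k], ],
                              .res3_of(model, code)))
        if (k <= n_units) {
          lines <- c(lines, fmt(an[["mid"]], k, c_i, ds$mid[ridx[k], ],
                                .res3_of(model, code)))
        }
      }
    }
  } else {
    ds <- derived_sites(topology, conf)
    B <- conf$branches
    for (r in seq_len(topology$n_res)) {
      c_i <- topology$chain[r]
      code <- topology$sequence[r]
      res3 <- .res3_of(model, code)
      resno <- r
      lines <- c(lines, fmt(an[["anchor"]], resno, c_i, A[r, ], res3))
      lines <- c(lines, fmt(an[["branch"]], resno, c_i, B[r, ], res3))
    }
    ## derived midpoint sites (p or P), attached to the 5'/N-terminal
    ## residue of their bond
    for (k in seq_len(nrow(topology$mids))) {
      r <- topology$mids$a1[k]
      lines <- c(lines, fmt(an[["mid"]], r, topology$mids$chain[k],
                            ds$mid[k, ], .res3_of(model,
                                                  topology$sequence[r])))
    }
  }
  lines
}

#' Write a coarse-grained PDB trace
#'
#' One pseudo-atom per site: CA/SC (+ peptide-midpoint P) for proteins,
#' S/B/P for nucleic acids, O4/SUG for polysaccharides. Occupancy and
#' B-factor columns are written as 1.00/0.00. Derived midpoint sites are
#' included for visualisation but ignored (recomputed) on reading.
#'
#' @param topology a `cg_topology`.
#' @param conf a `cg_conformation`, or a list of them (written as a
#'   multi-MODEL trajectory file).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_trace <- function(topology, conf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  confs <- if (inherits(conf, "cg_conformation")) list(conf) else conf
  multi <- length(confs) > 1
  for (m in seq_along(confs)) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    writeLines(.pdb_atom_lines(topology, confs[[m]]), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

#' Read a coarse-grained PDB trace
#'
#' Reconstructs the topology (from residue names and chain identifiers) and
#' conformation from a trace file written by [write_pdb_trace()] (or any
#' PDB with the same pseudo-atom naming). Atom records with names not in
#' the model's trace alphabet raise an error naming the offending line;
#' derived midpoint sites (P/SUG) are ignored and recomputed from the
#' anchors.
#'
#' @param path PDB file.
#' @param model chain class expected in the file.
#' @return List with `topology`, `conf` (first MODEL) and `frames` (all
#'   MODELs).
#' @export
read_pdb_trace <- function(path, model = .CG_MODELS) {
  model <- match.arg(model)
  if (!file.exists(path)) stop("no such file: ", path)
  an <- .PDB_ATOM[[model]]
  raw <- readLines(path)
  is_atom <- startsWith(raw, "ATOM")
  nm <- trimws(substr(raw[is_atom], 13, 16))
  bad <- !(nm %in% an)
  if (any(bad)) {
    stop(sprintf("unknown atom name '%s' at line %d of %s",
                 nm[bad][1], which(is_atom)[bad][1], path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep_a <- trimws(at$elety) == an[["anchor"]]
  keep_b <- nzchar(an[["branch"]]) & trimws(at$elety) == an[["branch"]]
  chains <- unique(at$chain[keep_a])
  ## sequence per chain from anchor (or branch) records
  seqs <- character(0)
  for (ch in chains) {
    rows <- which(keep_a & at$chain == ch)
    res3 <- at$resid[rows]
    if (model == "polysaccharide") res3 <- res3[-length(res3)]  # n+1 anchors
    seqs <- c(seqs, paste(.code_of_res3(model, res3), collapse = ""))
  }
  topology <- build_topology(seqs, model)
  nmod <- dim(pdb$xyz)[1]
  xyz_of <- function(m, rows) {
    idx <- as.vector(t(outer(rows - 1, 1:3, function(r, k) 3 * r + k)))
    matrix(pdb$xyz[m, idx], ncol = 3, byrow = TRUE)
  }
  a_rows <- which(keep_a)
  b_rows <- which(keep_b)
  frames <- lapply(seq_len(nmod), function(m) {
    structure(list(anchors = xyz_of(m, a_rows),
                   branches = if (length(b_rows)) xyz_of(m, b_rows) else
                     matrix(numeric(0), 0, 3)),
              class = "cg_conformation")
  })
  list(topology = topology, conf = frames[[1]], frames = frames)
}

#' Write a trajectory energy log as tab-separated text
#'
#' Columns: time (fs), each energy term (kcal/mol), weighted total, kinetic
#' energy and instantaneous kinetic temperature.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_log <- function(traj, path) {
  utils::write.table(traj$energy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Run configurations are YAML files holding the model kind, input paths,
#' MD/ladder/analysis settings and the seed; [run_config()] applies
#' defaults and validates.
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of settings (possibly partial).
#' @export
run_config <- function(cfg = list()) {
  base <- list(model = "protein", sequence = NULL, structure = NULL,
               forcefield = NULL, T = 300, dt = 5, ratio = 10, gamma = 0.1,
               steps = 1000, stride = 100, seed = 1,
               temperatures = NULL, mux = 1, exchange_interval = 100,
               cycles = 10, outdir = ".")
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (!base$model %in% .CG_MODELS) stop("unknown model: ", base$model)
  base
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
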