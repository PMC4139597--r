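## Deterministic test-system generators: a 20-residue protein helix start,
## a 2 x 12-nucleotide complementary duplex (near-native and extended), a
## 12-unit 1,4-linked glucose chain, and a two-state toy energy sampler for
## the reweighting/thermodynamics machinery.

.NT_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", U = "A")

#' Watson-Crick complement of a nucleotide sequence
#'
#' @param sequence one-letter nucleotide string.
#' @param reverse reverse the complement (5'->3' of the paired strand).
#' @return Complementary sequence string.
#' @export
complement_sequence <- function(sequence, reverse = TRUE) {
  cd <- .NT_COMPLEMENT[strsplit(sequence, "")[[1]]]
  if (anyNA(cd)) stop("cannot complement non-nucleotide codes")
  if (reverse) cd <- rev(cd)
  paste(cd, collapse = "")
}

## ideal right-handed duplex trace: anchors on a cylinder (radius 7 A,
## twist 36 deg, rise 3.4 A), bases pointing inwards; strand 2 antiparallel
## with its backbone rotated +140 deg about the helix axis
.build_duplex <- function(seq1, radius = 7, twist = 36, rise = 3.4,
                          groove = 140) {
  n <- nchar(seq1)
  seq2 <- complement_sequence(seq1)
  top <- build_topology(c(seq1, seq2), "nucleic_acid")
  geom <- chain_geometry("nucleic_acid")
  dB <- unname(unlist(geom$branch$lengths))
  names(dB) <- names(geom$branch$lengths)
  a1 <- deg2rad(twist * (seq_len(n) - 1))
  z1 <- rise * (seq_len(n) - 1)
  S1 <- cbind(radius * cos(a1), radius * sin(a1), z1)
  c1 <- strsplit(seq1, "")[[1]]
  B1 <- cbind((radius - dB[c1]) * cos(a1), (radius - dB[c1]) * sin(a1), z1)
  ## strand 2: residue j pairs with strand-1 residue i = n + 1 - j
  i2 <- n + 1 - seq_len(n)
  a2 <- a1[i2] + deg2rad(groove)
  z2 <- z1[i2]
  S2 <- cbind(radius * cos(a2), radius * sin(a2), z2)
  c2 <- strsplit(seq2, "")[[1]]
  B2 <- cbind((radius - dB[c2]) * cos(a2), (radius - dB[c2]) * sin(a2), z2)
  anchors <- rbind(S1, S2); branches <- rbind(B1, B2)
  dimnames(anchors) <- dimnames(branches) <- NULL
  conf <- structure(list(anchors = anchors, branches = branches),
                    class = "cg_conformation")
  list(topology = top, conf = conf)
}

#' Generate a deterministic test system
#'
#' Kinds:
#' \describe{
#'   \item{helix20}{20-residue poly-alanine chain in a compact helical
#'     start (virtual-bond angle 90 deg, dihedral 48 deg).}
#'   \item{duplex12}{two complementary 12-nucleotide strands, in an ideal
#'     right-handed duplex (`conf`) and as separated extended chains
#'     (`conf_extended`).}
#'   \item{sugar12}{12-unit alpha-D-glucose chain, extended.}
#'   \item{two_state_toy}{a two-state sampler for reweighting tests:
#'     `sample(T, n)` draws potential energies and folded indicators from
#'     an exact two-state model with melting enthalpy `dH = 50` kcal/mol
#'     and midpoint `Tm = 350` K (Gaussian width 2 kcal/mol around each
#'     state energy).}
#' }
#'
#' @param kind one of `"helix20"`, `"duplex12"`, `"sugar12"`,
#'   `"two_state_toy"`.
#' @param seed RNG seed (used by the toy sampler; the structural fixtures
#'   are fully deterministic).
#' @param dir optional directory: when given, FASTA/PDB (or TSV) files are
#'   written there and their paths returned in `files`.
#' @return Named list describing the system (see details above).
#' @export
make_fixture <- function(kind = c("helix20", "duplex12", "sugar12",
                                  "two_state_toy"),
                         seed = 1, dir = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    helix20 = {
      sq <- strrep("A", 20)
      top <- build_topology(sq, "protein")
      ic <- new_internal(
        top, d = rep(3.8, 19), theta = rep(deg2rad(90), 18),
        gamma = rep(deg2rad(48), 17),
        alpha = rep(deg2rad(50), 20), beta = rep(0, 20),
        d_branch = top$branches$d_b)
      list(kind = kind, sequence = sq, topology = top,
           conf = internal_to_cartesian(top, ic))
    },
    duplex12 = {
      sq <- "ACGTACGTACGT"
      dx <- .build_duplex(sq)
      ext <- place_extended(dx$topology)
      list(kind = kind, sequence = c(sq, complement_sequence(sq)),
           topology = dx$topology, conf = dx$conf, conf_extended = ext)
    },
    sugar12 = {
      sq <- strrep("a", 12)
      top <- build_topology(sq, "polysaccharide")
      list(kind = kind, sequence = sq, topology = top,
           conf = place_extended(top))
    },
    two_state_toy = {
      dH <- 50; Tm <- 350; width <- 2
      sampler <- function(T, n) {
        ## exact two-state occupancy: folded (energy -dH) vs unfolded (0)
        p_fold <- 1 / (1 + exp((dH / .RGAS) * (1 / Tm - 1 / T)))
        q <- stats::rbinom(n, 1, p_fold)
        U <- ifelse(q == 1, -dH, 0) + stats::rnorm(n, 0, width)
        list(U = U, q = q)
      }
      list(kind = kind, dH = dH, Tm = Tm, dS = dH / Tm, width = width,
           sample = sampler)
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    if (kind == "two_state_toy") {
      set.seed(seed)
      temps <- seq(320, 380, by = 10)
      rows <- do.call(rbind, lapply(temps, function(T) {
        s <- out$sample(T, 200)
        data.frame(T = T, U = s$U, q = s$q)
      }))
      f <- file.path(dir, "two_state_toy.tsv")
      utils::write.table(rows, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- f
    } else {
      fa <- file.path(dir, paste0(kind, ".fasta"))
      write_sequence(out$sequence, fa)
      pb <- file.path(dir, paste0(kind, ".pdb"))
      write_pdb_trace(out$topology, out$conf, pb)
      files <- c(fa, pb)
      if (!is.null(out$conf_extended)) {
        pe <- file.path(dir, paste0(kind, "_extended.pdb"))
        write_pdb_trace(out$topology, out$conf_extended, pe)
        files <- c(files, pe)
      }
    }
    out$files <- files
  }
  out
}
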