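# Synthetic-data generators.
#
# Everything downstream (CSR mapping, composition indices, kinetics,
# activity profiles) can be exercised on generated inputs with known
# ground truth, so the whole pipeline runs without downloads. All
# generators are pure functions of their spec including the seed.
#
# The canonical CSR blocks below are synthetic fixture constants modelled
# on the published motif descriptions (pentapeptide variants in CSR V,
# invariant Trp in CSR VI, Tyr-GEE terminating CSR VII, terminal His in
# CSR II, aromatic position in CSR III, D/E/D triad in CSR II/III/IV);
# they are not copied from any real enzyme.

# Run code under a fixed seed, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# block sequence, diagnostic offset (NA = positional convention), and the
# offset of any triad residue within the block
CSR_BLOCKS <- function(subfamily) {
  variants <- list(
    oligo16glucosidase = list(V = "QPDLN", VI = "GLSTR", VII = "GVPLIAGEE",
                              II_end = "S", III_diag = "G"),
    neopullulanase = list(V = "MPKLN", VI = "GLSTR", VII = "GVPLIYGEE",
                          II_end = "S", III_diag = "G"),
    gh13_36 = list(V = "MPDLN", VI = "GWSTR", VII = "GVPLIYGEE",
                   II_end = "H", III_diag = "W"),
    gh13_36_atypical = list(V = "QPDLN", VI = "GWSTR", VII = "GVPLIYGEE",
                            II_end = "F", III_diag = "G")
  )
  v <- variants[[subfamily]]
  if (is.null(v)) {
    stop("unknown subfamily '", subfamily, "'; use one of ",
         paste(names(variants), collapse = ", "))
  }
  list(
    I   = list(seq = "DVVINH", diag = NA_integer_, triad = NA_integer_),
    II  = list(seq = paste0("GFRLDAVK", v$II_end), diag = NA_integer_,
               triad = 5L),
    III = list(seq = paste0("EV", v$III_diag, "NS"), diag = 3L, triad = 1L),
    IV  = list(seq = "FVDNHD", diag = NA_integer_, triad = 6L),
    V   = list(seq = v$V, diag = 1L, triad = NA_integer_),
    VI  = list(seq = v$VI, diag = 2L, triad = NA_integer_),
    VII = list(seq = v$VII, diag = NA_integer_, triad = NA_integer_)
  )
}

# Typical globular-protein residue frequencies (rounded, renormalized).
DEFAULT_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, E = 0.063,
  Q = 0.043, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.014,
  Y = 0.032, V = 0.065)

#' Generate a GH13-like protein with planted CSRs
#'
#' Draws a background sequence from a residue frequency vector, plants the
#' seven canonical CSR blocks of the requested subfamily at the given
#' offsets, then applies point substitutions strictly outside the CSR
#' windows. Because the background draw precedes the mutation draw in the
#' RNG stream, two specs differing only in `mutation_rate` share the same
#' background — mutated queries align cleanly to their unmutated exemplar.
#'
#' @param subfamily One of `"oligo16glucosidase"`, `"neopullulanase"`,
#'   `"gh13_36"`, `"gh13_36_atypical"` (the last mirrors a GH13_36-like
#'   enzyme carrying QPDLN in CSR V).
#' @param length Total sequence length in residues (default 520).
#' @param csr_offsets Named or ordered integer vector of seven window start
#'   positions (default: evenly spread).
#' @param background Residue frequency vector over the 20 standard amino
#'   acids (summing to 1).
#' @param mutation_rate Per-residue substitution probability outside the
#'   CSR windows.
#' @param seed RNG seed.
#' @param id Record id (default derived from the subfamily and seed).
#' @return A list with `record` (a protein [seq_record()]) and `reference`
#'   (the ground-truth [csr_reference()] annotation).
#' @export
gen_gh13_sequence <- function(subfamily, length = 520L,
                              csr_offsets = NULL,
                              background = DEFAULT_BACKGROUND,
                              mutation_rate = 0, seed = 1L,
                              id = sprintf("syn_%s_s%d", subfamily, seed)) {
  stopifnot(length >= 120L, mutation_rate >= 0, mutation_rate <= 1)
  background <- background / sum(background)
  blocks <- CSR_BLOCKS(subfamily)
  widths <- vapply(blocks, function(b) nchar(b$seq), 0L)
  if (is.null(csr_offsets)) {
    # seven windows spread over the chain, GH13-style: CSRs populate the
    # catalytic domain, leaving an N-terminal stretch and a C-terminal tail
    anchors <- round(seq(0.15, 0.75, length.out = 7) * length)
    csr_offsets <- as.integer(anchors)
  }
  stopifnot(length(csr_offsets) == 7L)
  ends <- csr_offsets + widths - 1L
  if (any(csr_offsets[-1] <= ends[-7]) || ends[7] > length ||
      csr_offsets[1] < 1L) {
    stop("CSR placements must be ordered, non-overlapping and inside the sequence")
  }
  chars <- with_seed(seed, {
    x <- sample(names(background), length, replace = TRUE,
                prob = background)
    in_csr <- rep(FALSE, length)
    for (i in seq_along(blocks)) {
      span <- csr_offsets[i]:ends[i]
      x[span] <- strsplit(blocks[[i]]$seq, "")[[1]]
      in_csr[span] <- TRUE
    }
    if (mutation_rate > 0) {
      outside <- which(!in_csr)
      hit <- outside[stats::runif(length(outside)) < mutation_rate]
      for (p in hit) {
        x[p] <- sample(setdiff(names(background), x[p]), 1L)
      }
    }
    x
  })
  residues <- paste(chars, collapse = "")
  rec <- seq_record(id, residues, "protein",
                    description = paste("synthetic GH13-like,", subfamily),
                    source = "synthetic")
  windows <- data.frame(
    label = CSR_LABELS, start = csr_offsets, end = ends,
    diag_offset = vapply(blocks, function(b) b$diag, NA_integer_),
    stringsAsFactors = FALSE)
  triad_off <- vapply(blocks, function(b) b$triad, NA_integer_)
  triad <- (csr_offsets + triad_off - 1L)[!is.na(triad_off)]
  list(record = rec,
       reference = csr_reference(rec, windows, subfamily_tag = subfamily,
                                 triad = triad))
}

#' Default synthetic CSR reference panel
#'
#' Four zero-noise exemplars, one per subfamily preset, sharing one
#' background seed so that any query generated from the same seed differs
#' from its exemplar only in the planted diagnostics (and any mutations).
#' Clearly synthetic; real UniProt-derived panels are supplied by the user
#' through [read_csr_panel()].
#'
#' @param seed Background seed shared by the exemplars.
#' @param length Sequence length of the exemplars.
#' @return A list of four [csr_reference()] objects.
#' @export
default_csr_panel <- function(seed = 42L, length = 520L) {
  subs <- c("oligo16glucosidase", "neopullulanase", "gh13_36",
            "gh13_36_atypical")
  lapply(subs, function(sf) {
    gen_gh13_sequence(sf, length = length, mutation_rate = 0, seed = seed,
                      id = paste0("panel_", sf))$reference
  })
}

#' Generate a sequence with prescribed R/K/D/E counts
#'
#' Plants exact numbers of Arg, Lys, Asp and Glu at random positions; the
#' remaining positions are drawn uniformly from the 16 other standard
#' residues, so the adaptation indices of the output are fixed by
#' construction.
#'
#' @param length Total residues.
#' @param n_arg,n_lys,n_asp,n_glu Planted counts (sum `<= length`).
#' @param seed RNG seed.
#' @param id Record id.
#' @return A protein [seq_record()].
#' @export
gen_composition_sequence <- function(length, n_arg, n_lys, n_asp, n_glu,
                                     seed = 1L, id = "syn_composition") {
  counts <- c(R = n_arg, K = n_lys, D = n_asp, E = n_glu)
  stopifnot(all(counts >= 0), sum(counts) <= length)
  others <- setdiff(names(DEFAULT_BACKGROUND), names(counts))
  chars <- with_seed(seed, {
    x <- sample(others, length, replace = TRUE)
    planted <- sample(length, sum(counts))
    x[planted] <- rep(names(counts), counts)
    x
  })
  seq_record(id, paste(chars, collapse = ""), "protein",
             description = "synthetic composition-controlled sequence",
             source = "synthetic")
}

#' Generate Michaelis-Menten velocity data
#'
#' `v_i = Vmax s_i / (Km + s_i) * (1 + eps_i)` with multiplicative
#' Gaussian noise `eps_i ~ N(0, noise_sd)` — assay coefficients of
#' variation scale with signal. Defaults reproduce the study design: a
#' doubling soluble-starch grid from 0.125% to 2% w/v (1.25-20 mg/mL).
#'
#' @param km,vmax True parameters (defaults 2.53 mg/mL, 0.125 mg/mL/min).
#' @param substrate Substrate grid in mg/mL.
#' @param noise_sd Multiplicative noise SD as a fraction (default 0.05).
#' @param n_replicates Replicates per substrate level.
#' @param seed RNG seed.
#' @return A [kinetic_dataset()].
#' @export
gen_mm_data <- function(km = 2.53, vmax = 0.125,
                        substrate = c(1.25, 2.5, 5, 10, 20),
                        noise_sd = 0.05, n_replicates = 1L, seed = 1L) {
  stopifnot(km > 0, vmax > 0, noise_sd >= 0, n_replicates >= 1L)
  s <- rep(substrate, each = n_replicates)
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(s), 0, noise_sd))
  } else 0
  v <- mm_velocity(s, km, vmax) * (1 + eps)
  kinetic_dataset(s, v, notes = sprintf("synthetic, Km=%g Vmax=%g", km, vmax))
}

#' Generate a unimodal activity-vs-condition profile
#'
#' Gaussian-shaped relative-activity curve
#' `100 * exp(-(x - optimum)^2 / (2 sigma^2))` with the width solved so a
#' prescribed anchor point is honored exactly (e.g. an optimum of 25 deg C
#' with 53.2% relative activity at 0 deg C). Multiplicative noise is added
#' and the curve renormalized to a 100% maximum.
#'
#' @param optimum Condition of maximal activity (default 25).
#' @param reference_condition,reference_relative_pct The anchored point;
#'   the reference must differ from the optimum and its relative activity
#'   must lie in (0, 100).
#' @param grid Condition grid (default 0-60 in steps of 5).
#' @param noise_sd Multiplicative noise SD as a fraction.
#' @param seed RNG seed.
#' @return An `activity_profile` (max-normalized).
#' @export
gen_activity_profile <- function(optimum = 25, reference_condition = 0,
                                 reference_relative_pct = 53.2,
                                 grid = seq(0, 60, by = 5), noise_sd = 0,
                                 seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (reference_relative_pct <= 0 || reference_relative_pct >= 100) {
    stop("reference_relative_pct must lie strictly between 0 and 100")
  }
  if (reference_condition == optimum) {
    stop("degenerate anchor: reference condition equals the optimum, ",
         "so no finite curve width satisfies it")
  }
  sigma2 <- (reference_condition - optimum)^2 /
    (2 * log(100 / reference_relative_pct))
  rel <- 100 * exp(-(grid - optimum)^2 / (2 * sigma2))
  if (noise_sd > 0) {
    rel <- rel * (1 + with_seed(seed, stats::rnorm(length(rel), 0, noise_sd)))
    rel <- pmax(rel, 0)
  }
  relative_activity(grid, rel, mode = "max")
}
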