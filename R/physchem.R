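# Composition-based physicochemical and adaptation indices.
#
# Two composition indices carry the adaptation signal: the Arg/(Arg+Lys)
# ratio (low in cold-adapted, flexible proteins — Arg stabilizes through
# salt bridges and H-bonds) and the acidic amino-acid excess
# (Asp+Glu)% − (Arg+Lys)% (high in halophilic/halotolerant proteins, whose
# acidic surfaces hold a hydrated ion network at high salinity).

# Average residue masses in Da (Expasy-style average isotopic composition);
# a peptide's mass is the sum of residue masses plus one water.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

# Ionizable-group pKa sets. "bjellqvist" is the ProtParam table, including
# its residue-specific N- and C-terminal pKas; "emboss" matches EMBOSS iep.
PKA_SETS <- list(
  bjellqvist = list(
    nterm = c(default = 7.5, A = 7.59, M = 7.0, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.7),
    cterm = c(default = 3.55, D = 4.55, E = 4.75),
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ),
  emboss = list(
    nterm = c(default = 8.6),
    cterm = c(default = 3.6),
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

AA20 <- names(AVERAGE_RESIDUE_MASS)

aa_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  table(factor(chars, levels = c(AA20, "X")))
}

#' Amino-acid composition profile
#'
#' Per-residue fractions and the adaptation-relevant percentage indices.
#' `X` residues are excluded from every denominator and reported in
#' `n_excluded`. Values are stored at full precision; round only for
#' presentation.
#'
#' @param seq Protein string over the 20 standard residues (`X` allowed).
#' @return An object of class `composition_profile`: `length` (residues
#'   counted), `n_excluded`, `fractions` (named, sums to 1), `arg_pct`,
#'   `lys_pct`, `arg_ratio` (Arg/(Arg+Lys), `NA` and flagged when
#'   Arg+Lys = 0), `acidic_pct` (Asp+Glu), `basic_pct` (Arg+Lys) and
#'   `acidic_excess_pct`.
#' @export
composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("'seq' must be a non-empty protein string")
  }
  cnt <- aa_counts(seq)
  bad <- nchar(seq) - sum(cnt)
  if (bad > 0L) stop("sequence contains ", bad, " non-standard residue(s)")
  n_x <- cnt[["X"]]
  cnt <- cnt[AA20]
  n <- sum(cnt)
  if (n == 0L) stop("no standard residues in sequence")
  frac <- as.numeric(cnt) / n
  names(frac) <- AA20
  pct <- function(r) 100 * sum(frac[r])
  rk <- cnt[["R"]] + cnt[["K"]]
  structure(
    list(length = n, n_excluded = n_x, fractions = frac,
         arg_pct = pct("R"), lys_pct = pct("K"),
         arg_ratio = if (rk > 0) cnt[["R"]] / rk else NA_real_,
         arg_ratio_defined = rk > 0,
         acidic_pct = pct(c("D", "E")), basic_pct = pct(c("R", "K")),
         acidic_excess_pct = pct(c("D", "E")) - pct(c("R", "K"))),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<composition_profile> %d aa (%d X excluded)\n",
    "  Arg %.1f%%  Lys %.1f%%  Arg/(Arg+Lys) %s\n",
    "  acidic (D+E) %.1f%%  basic (R+K) %.1f%%  excess %.1f%%\n"),
    x$length, x$n_excluded, x$arg_pct, x$lys_pct,
    if (x$arg_ratio_defined) sprintf("%.2f", x$arg_ratio) else "undefined",
    x$acidic_pct, x$basic_pct, x$acidic_excess_pct))
  invisible(x)
}

#' Acidic amino-acid excess
#'
#' `acidic_pct - basic_pct`, the halotolerance index: (Asp+Glu)% minus
#' (Arg+Lys)%.
#'
#' @param acidic_pct Percentage of acidic residues (Asp+Glu).
#' @param basic_pct Percentage of basic residues (Arg+Lys).
#' @return The excess, in percentage points.
#' @export
acidic_excess <- function(acidic_pct, basic_pct) {
  stopifnot(all(acidic_pct >= 0), all(basic_pct >= 0))
  acidic_pct - basic_pct
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass. Non-standard
#' residues (including `X`) are an error naming the first offending
#' position.
#'
#' @param seq Protein string over the 20 standard residues.
#' @return Mass in Da.
#' @export
molecular_weight <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  m <- AVERAGE_RESIDUE_MASS[chars]
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stop("non-standard residue '", chars[i], "' at position ", i)
  }
  sum(m) + WATER_MASS
}

net_charge <- function(counts, nterm_aa, cterm_aa, pka, pH) {
  pk_n <- if (nterm_aa %in% names(pka$nterm)) pka$nterm[[nterm_aa]]
          else pka$nterm[["default"]]
  pk_c <- if (cterm_aa %in% names(pka$cterm)) pka$cterm[[cterm_aa]]
          else pka$cterm[["default"]]
  pos <- 1 / (1 + 10^(pH - pk_n))
  for (r in names(pka$positive)) {
    pos <- pos + counts[[r]] / (1 + 10^(pH - pka$positive[[r]]))
  }
  neg <- 1 / (1 + 10^(pk_c - pH))
  for (r in names(pka$negative)) {
    neg <- neg + counts[[r]] / (1 + 10^(pka$negative[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge (both termini plus the
#' Arg/Lys/His and Asp/Glu/Cys/Tyr side chains) crosses zero, found by
#' bisection on \[0, 14\] to a tolerance of 0.005 and reported at 0.01
#' resolution. The net charge is strictly decreasing in pH, so the root is
#' unique.
#'
#' @param seq Protein string (`X` allowed; `X` carries no ionizable group).
#' @param pka_set Name of a shipped pKa table: `"bjellqvist"` (ProtParam,
#'   the default) or `"emboss"`.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_set = "bjellqvist") {
  if (!pka_set %in% names(PKA_SETS)) {
    stop("unknown pKa set '", pka_set, "'; available: ",
         paste(names(PKA_SETS), collapse = ", "))
  }
  pka <- PKA_SETS[[pka_set]]
  cnt <- aa_counts(seq)
  if (nchar(seq) - sum(cnt) > 0L) stop("non-standard residues in sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  lo <- 0; hi <- 14
  f_lo <- net_charge(cnt, chars[1], chars[length(chars)], pka, lo)
  f_hi <- net_charge(cnt, chars[1], chars[length(chars)], pka, hi)
  if (f_lo <= 0 || f_hi >= 0) {
    stop("charge curve has no zero crossing on [0, 14]")  # unreachable with termini
  }
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (net_charge(cnt, chars[1], chars[length(chars)], pka, mid) > 0) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  round((lo + hi) / 2, 2)
}

#' Adaptation comparison table
#'
#' Tabulates the cold-adaptation and halotolerance indices for a set of
#' composition profiles, one labelled row each, in the order given.
#'
#' @param profiles List of [composition()] results.
#' @param labels Character vector of row labels, same length.
#' @param feature Optional character vector of free-text annotations
#'   (e.g. "cold active"); recycled if length 1.
#' @return A data.frame with columns `label`, `feature`, `length_aa`,
#'   `arg_pct`, `lys_pct`, `arg_ratio`, `acidic_pct`, `basic_pct`,
#'   `acidic_excess_pct`, `n_excluded`.
#' @export
adaptation_report <- function(profiles, labels, feature = "") {
  stopifnot(length(profiles) >= 1L, length(labels) == length(profiles))
  feature <- rep_len(feature, length(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(label = labels[i], feature = feature[i], length_aa = p$length,
               arg_pct = p$arg_pct, lys_pct = p$lys_pct,
               arg_ratio = p$arg_ratio, acidic_pct = p$acidic_pct,
               basic_pct = p$basic_pct,
               acidic_excess_pct = p$acidic_excess_pct,
               n_excluded = p$n_excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
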