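#' Chromatin-state enrichment of CpG classes
#'
#' For each CpG class, compares the chromatin-state distribution of
#' in-class CpGs against all remaining CpGs with a chi-square test on the
#' 2 x states contingency table (no continuity correction, so the statistic
#' is exactly \code{sum((O-E)^2/E)}). Signed Pearson residuals
#' \code{(O-E)/sqrt(E)} of the in-class row flag enrichment (positive) or
#' depletion (negative) per state. States whose expected in-class count is
#' below \code{min_expected} are merged into \code{"other"} with a warning.
#' Q-values are BH-adjusted across the class tests.
#'
#' @param classes Character vector of class labels per CpG; the label
#'   \code{"none"} marks background-only CpGs and gets no test.
#' @param states Character vector of chromatin-state labels, same length.
#' @param min_expected Expected-count floor below which a state is merged.
#' @return data.frame: one row per (class, state):
#'   \code{class}, \code{state}, \code{chisq}, \code{df}, \code{p}, \code{q}
#'   (shared within a class), \code{residual}, \code{direction}.
#' @export
chromatin_enrichment <- function(classes, states, min_expected = 1) {
  if (length(classes) != length(states)) stop("length mismatch")
  if (length(unique(states)) < 2)
    stop("need at least 2 chromatin states")
  lvls <- setdiff(unique(classes), "none")
  if (length(lvls) < 1)
    stop("need at least one non-background class")
  rows <- lapply(lvls, function(cl) {
    st <- states
    tab <- table(factor(classes == cl, levels = c(TRUE, FALSE)), st)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- expected[1, ] < min_expected
    if (any(low)) {
      if (all(low)) stop("all states fall below the expected-count floor")
      warning(sprintf("class '%s': %d state(s) merged into 'other'",
                      cl, sum(low)))
      st[st %in% colnames(tab)[low]] <- "other"
      tab <- table(factor(classes == cl, levels = c(TRUE, FALSE)), st)
    }
    ct <- stats::chisq.test(tab, correct = FALSE)
    data.frame(class = cl, state = colnames(tab),
               chisq = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value,
               residual = ct$residuals[1, ],
               direction = sign(ct$residuals[1, ]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class_p <- vapply(split(out$p, out$class), `[`, numeric(1), 1)
  class_q <- bh_fdr(class_p)
  out$q <- class_q[out$class]
  out
}

#' Epigenetic-clock enrichment of a CpG class
#'
#' Tests whether a class of CpGs is over- or under-represented among the
#' CpGs of a published epigenetic clock, restricted to the clock's own
#' background (each clock was trained on a different probe pool, so each
#' gets its own background). The 2x2 table (in clock vs not) x (in class vs
#' not) is tested with Fisher's exact test; the odds ratio is the sample
#' cross-product, with a Haldane 0.5 correction when a cell is zero.
#'
#' @param class_cpgs Character vector of CpG ids in the class.
#' @param clock List with \code{name}, \code{cpgs} (clock CpG ids) and
#'   \code{background} (the probe pool the clock was built from;
#'   \code{cpgs} must be a subset).
#' @param universe CpG ids actually analyzed; the test is run on
#'   \code{intersect(background, universe)}.
#' @return One-row data.frame: \code{clock}, \code{or}, \code{p},
#'   \code{direction}, and the 2x2 counts.
#' @export
clock_enrichment <- function(class_cpgs, clock, universe) {
  bg <- intersect(clock$background, universe)
  if (length(bg) == 0) stop("clock background does not intersect the universe")
  if (!all(clock$cpgs %in% clock$background))
    stop("clock CpG set must be a subset of its background")
  in_clock <- bg %in% clock$cpgs
  in_class <- bg %in% class_cpgs
  a <- sum(in_clock & in_class)
  b <- sum(in_clock & !in_class)
  c_ <- sum(!in_clock & in_class)
  d <- sum(!in_clock & !in_class)
  # a zero margin (e.g. the class covers the whole background) carries no
  # association information: report OR = 1
  or <- if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
    1
  } else if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
  data.frame(clock = clock$name, or = or, p = p,
             direction = ifelse(or >= 1, 1, -1),
             n_clock_class = a, n_clock_other = b,
             n_bg_class = c_, n_bg_other = d,
             stringsAsFactors = FALSE)
}

#' Clock enrichment across a panel of clocks
#'
#' Runs [clock_enrichment()] for every clock and BH-adjusts the p-values.
#'
#' @param class_cpgs CpG ids in the class of interest.
#' @param clocks List of clock definitions (see [clock_enrichment()]).
#' @param universe Analyzed CpG universe.
#' @param q_threshold Significance threshold on the FDR (default 0.005).
#' @return data.frame with one row per clock, including \code{q} and
#'   \code{significant}.
#' @export
clock_enrichment_table <- function(class_cpgs, clocks, universe,
                                   q_threshold = 0.005) {
  out <- do.call(rbind, lapply(clocks, clock_enrichment,
                               class_cpgs = class_cpgs, universe = universe))
  out$q <- bh_fdr(out$p)
  out$significant <- call_significant(out$q, q_threshold)
  out
}
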