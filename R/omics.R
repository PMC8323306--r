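# Statistics for lipidomics and targeted-proteomics tables: class-standard
# normalization, stratified differential abundance with FDR and
# fold-change gates, diet-response scatter normalization, correlations
# with an insulin-sensitivity index, and a two-way factorial screen.

#' Construct an analyte-by-sample omics table
#'
#' Shared container for lipidomics and proteomics stages: a non-negative
#' intensity/concentration matrix with unique analyte identifiers, a
#' sample sheet with complete (age, diet) labels, and (for lipids) a
#' per-analyte class annotation.
#'
#' @param values Numeric matrix, analytes x samples, with dimnames.
#' @param samples data.frame with columns `sample`, `age`, `diet`;
#'   `sample` must cover every column of `values`.
#' @param classes Optional named character vector (or data.frame with
#'   columns `analyte`, `class`) assigning each analyte to a lipid class.
#' @return Object of class `omics_table`.
#' @export
omics_table <- function(values, samples, classes = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have analyte rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate analyte identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(values < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  need <- c("sample", "age", "diet")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(values), samples$sample)
  if (length(missing))
    stop("samples sheet lacks label rows for: ",
         paste(missing, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  if (any(is.na(samples$age)) || any(is.na(samples$diet)))
    stop("every sample needs both age and diet labels")
  if (!is.null(classes)) {
    if (is.data.frame(classes))
      classes <- stats::setNames(classes$class, classes$analyte)
    missing_cl <- setdiff(rownames(values), names(classes))
    if (length(missing_cl))
      stop("class annotation missing for ", length(missing_cl),
           " analyte(s), e.g. ", missing_cl[1])
    classes <- classes[rownames(values)]
  }
  structure(list(values = values, samples = samples, classes = classes),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat("<omics_table>", nrow(x$values), "analytes x", ncol(x$values),
      "samples\n")
  print(table(x$samples$age, x$samples$diet))
  invisible(x)
}

#' Normalize lipid intensities to class internal standards
#'
#' Each analyte is divided by the internal-standard intensity of its lipid
#' class; classes without a standard fall back to the mean of all provided
#' standards.
#'
#' @param tab An [omics_table()] with class annotation.
#' @param standards Named numeric vector of standard intensities per class.
#' @return A normalized [omics_table()].
#' @export
normalize_to_class_standard <- function(tab, standards) {
  if (is.null(tab$classes))
    stop("table has no class annotation; cannot normalize to standards")
  if (any(standards == 0))
    stop("zero standard intensity for class(es): ",
         paste(names(standards)[standards == 0], collapse = ", "))
  fallback <- mean(standards)
  divisor <- ifelse(tab$classes %in% names(standards),
                    standards[tab$classes], fallback)
  tab$values <- tab$values / divisor
  tab
}

# --- FDR ---------------------------------------------------------------------

#' Benjamini-Hochberg step-up q-values
#'
#' Own implementation (kept independent of `stats::p.adjust` so the two
#' can check each other): q_(i) = min_{j >= i} p_(j) * m / j.
#'
#' @param p Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
fdr_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Two-stage adaptive step-up q-values
#'
#' Benjamini-Krieger-Yekutieli two-stage procedure: a first BH pass at
#' level Q/(1+Q) estimates the number of true nulls m0 = m - r1, and the
#' second pass scales the BH q-values by m0/m (and by 1/(1+Q)).
#'
#' @param p p-values.
#' @param Q Target FDR level used by the adaptive stage.
#' @return Adjusted q-values in the input order.
#' @export
fdr_two_stage <- function(p, Q = 0.05) {
  m <- length(p)
  q1 <- fdr_bh(p)
  r1 <- sum(q1 <= Q / (1 + Q))
  m0 <- m - r1
  if (m0 <= 0) return(rep(0, m))
  pmin(fdr_bh(p) * (m0 / m) / (1 + Q), 1)
}

# vectorised two-sample Student t (equal variances), rows of x vs rows of y
.row_t_test <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate variance: identical values in both groups => p = 1
  degen <- se == 0
  if (any(degen)) {
    p[degen & m1 == m2] <- 1
    t[degen & m1 == m2] <- 0
    p[degen & m1 != m2] <- 0
    t[degen & m1 != m2] <- sign(m1 - m2)[degen & m1 != m2] * Inf
  }
  list(t = t, p = p, df = df)
}

#' Differential abundance between diets within one age stratum
#'
#' For the chosen age group: log2-transform (zeros replaced by half the
#' analyte's smallest positive value), mean-centre per analyte across the
#' stratum, Student's t-test HFD vs LFD per analyte, FDR adjustment at
#' Q = 5%, linear-scale fold change of group means, and the two-gate
#' significance flag: q < 0.05 AND (FC >= 1.5 OR FC <= 0.66).
#'
#' @param tab An [omics_table()].
#' @param age Age stratum to compare within (a value of
#'   `tab$samples$age`).
#' @param fdr `"bh"` (Benjamini-Hochberg step-up, default) or
#'   `"two-stage"` (adaptive step-up).
#' @param q_threshold,fc_up,fc_down Gate thresholds.
#' @return data.frame of class `bx_differential` with per-analyte columns
#'   `analyte`, `class`, `mean_lfd`, `mean_hfd`, `fold_change`, `t`, `p`,
#'   `q`, `significant`; the FDR variant used is in
#'   `attr(, "fdr_method")`.
#' @export
differential <- function(tab, age, fdr = c("bh", "two-stage"),
                         q_threshold = 0.05, fc_up = 1.5, fc_down = 0.66) {
  fdr <- match.arg(fdr)
  keep <- tab$samples$age == age
  if (!any(keep)) stop("no samples with age '", age, "'")
  v <- tab$values[, keep, drop = FALSE]
  diet <- tab$samples$diet[keep]
  if (sum(diet == "HFD") < 2 || sum(diet == "LFD") < 2)
    stop("need >= 2 samples per diet within the age stratum")

  lv <- .safe_log2(v)
  lv <- lv - rowMeans(lv)  # mean-centring; location shift, t unchanged
  tt <- .row_t_test(lv[, diet == "HFD", drop = FALSE],
                    lv[, diet == "LFD", drop = FALSE])
  q <- if (fdr == "bh") fdr_bh(tt$p) else fdr_two_stage(tt$p, q_threshold)
  mean_hfd <- rowMeans(v[, diet == "HFD", drop = FALSE])
  mean_lfd <- rowMeans(v[, diet == "LFD", drop = FALSE])
  fc <- mean_hfd / mean_lfd
  sig <- (q < q_threshold) & (fc >= fc_up | fc <= fc_down)
  out <- data.frame(
    analyte = rownames(v),
    class = if (is.null(tab$classes)) NA_character_ else
      unname(tab$classes),
    mean_lfd = mean_lfd, mean_hfd = mean_hfd, fold_change = fc,
    t = tt$t, p = tt$p, q = q, significant = sig,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("bx_differential", class(out))
  attr(out, "fdr_method") <- fdr
  attr(out, "age") <- age
  out
}

# zeros -> half the smallest positive value of that analyte (documented,
# configurable through pre-processing); all-zero rows get a tiny floor
.safe_log2 <- function(v) {
  if (any(v == 0)) {
    repl <- apply(v, 1, function(r) {
      pos <- r[r > 0]
      if (length(pos)) min(pos) / 2 else NA_real_
    })
    idx <- which(v == 0, arr.ind = TRUE)
    v[idx] <- repl[idx[, 1]]
    if (anyNA(v)) v[is.na(v)] <- .Machine$double.eps
  }
  log2(v)
}

#' Diet-response scatter coordinates
#'
#' Normalizes each analyte to its mean over all animals (both ages, both
#' diets), then returns the LFD and HFD group means per age. Analytes on
#' the identity line are not regulated by diet.
#'
#' @param tab An [omics_table()].
#' @return data.frame `analyte`, `class`, `age`, `mean_lfd`, `mean_hfd`
#'   (normalized units). Analytes with a zero grand mean are dropped with
#'   a warning.
#' @export
diet_response_scatter <- function(tab) {
  gm <- rowMeans(tab$values)
  drop <- gm == 0
  if (any(drop)) {
    warning("dropping analyte(s) with zero grand mean: ",
            paste(rownames(tab$values)[drop], collapse = ", "))
  }
  v <- tab$values[!drop, , drop = FALSE] / gm[!drop]
  cl <- if (is.null(tab$classes)) NULL else tab$classes[!drop]
  out <- do.call(rbind, lapply(unique(tab$samples$age), function(a) {
    sel_l <- tab$samples$age == a & tab$samples$diet == "LFD"
    sel_h <- tab$samples$age == a & tab$samples$diet == "HFD"
    data.frame(analyte = rownames(v),
               class = if (is.null(cl)) NA_character_ else unname(cl),
               age = a,
               mean_lfd = rowMeans(v[, sel_l, drop = FALSE]),
               mean_hfd = rowMeans(v[, sel_h, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Correlate analytes with a per-sample index
#'
#' Pearson correlation of each analyte across all samples (pooled over
#' groups) against an index such as MISI, with the two-sided t-based
#' p-value.
#'
#' @param tab An [omics_table()].
#' @param index Named numeric vector (names = samples) or numeric in
#'   column order.
#' @return data.frame `analyte`, `class`, `r`, `p`, `n`, `defined`
#'   (`FALSE` where either vector has zero variance).
#' @export
correlate_with_index <- function(tab, index) {
  if (!is.null(names(index))) {
    missing <- setdiff(colnames(tab$values), names(index))
    if (length(missing))
      stop("index missing for sample(s): ", paste(missing, collapse = ", "))
    index <- index[colnames(tab$values)]
  }
  n <- length(index)
  if (n != ncol(tab$values))
    stop("index length must match the number of samples")
  if (n < 3) stop("need >= 3 paired observations")
  keep <- is.finite(index)
  v <- tab$values[, keep, drop = FALSE]
  idx <- index[keep]
  n <- length(idx)
  sd_a <- apply(v, 1, stats::sd)
  defined <- sd_a > 0 & stats::sd(idx) > 0
  r <- rep(NA_real_, nrow(v))
  r[defined] <- as.numeric(stats::cor(t(v[defined, , drop = FALSE]), idx))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(analyte = rownames(v),
             class = if (is.null(tab$classes)) NA_character_ else
               unname(tab$classes),
             r = r, p = ifelse(defined, p, NA_real_), n = n,
             defined = defined, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way factorial screen (age x diet)
#'
#' Per-analyte two-factor fixed-effects decomposition on log2 values with
#' marginal (Type-II) sums of squares — main effects are tested adjusted
#' for each other, the interaction adjusted for both, all against the
#' residual of the full interaction model — plus effect directions from
#' unweighted marginal cell-mean differences (HFD - LFD, old - young).
#'
#' @param tab An [omics_table()].
#' @param log2_transform Apply log2 first (default TRUE, matching the
#'   intensity scale of the differential stage).
#' @return data.frame `analyte`, `p_age`, `p_diet`, `p_interaction`,
#'   `dir_age`, `dir_diet` (+1/-1/0 signs).
#' @export
factorial_screen <- function(tab, log2_transform = TRUE) {
  s <- tab$samples
  cells <- table(s$age, s$diet)
  if (any(cells == 0) || nrow(cells) < 2 || ncol(cells) < 2)
    stop("all four age x diet cells must be non-empty")
  y <- if (log2_transform) .safe_log2(tab$values) else tab$values
  A <- factor(s$age); B <- factor(s$diet)
  rss <- function(formula_terms) {
    X <- stats::model.matrix(formula_terms)
    qr_x <- qr(X)
    resid <- t(y) - X %*% qr.coef(qr_x, t(y))
    colSums(resid^2)
  }
  rss_a <- rss(~A); rss_b <- rss(~B)
  rss_ab <- rss(~A + B); rss_full <- rss(~A * B)
  n <- ncol(y)
  df_e <- n - 4L
  if (df_e < 1) stop("need more samples than model parameters")
  mse <- rss_full / df_e
  f_age <- (rss_b - rss_ab) / mse       # SS(A | B), 1 df
  f_diet <- (rss_a - rss_ab) / mse      # SS(B | A), 1 df
  f_int <- (rss_ab - rss_full) / mse    # SS(AB | A, B), 1 df
  p_of <- function(f) stats::pf(pmax(f, 0), 1, df_e, lower.tail = FALSE)

  cm <- function(age, diet)
    rowMeans(tab$values[, s$age == age & s$diet == diet, drop = FALSE])
  ages <- sort(unique(as.character(s$age)))
  diets <- sort(unique(as.character(s$diet)))
  # canonical orientations: old - young, HFD - LFD when those labels exist
  a_hi <- if ("old" %in% ages) "old" else ages[2]
  a_lo <- setdiff(ages, a_hi)[1]
  b_hi <- if ("HFD" %in% diets) "HFD" else diets[2]
  b_lo <- setdiff(diets, b_hi)[1]
  dir_age <- sign((cm(a_hi, b_lo) + cm(a_hi, b_hi)) / 2 -
                  (cm(a_lo, b_lo) + cm(a_lo, b_hi)) / 2)
  dir_diet <- sign((cm(a_lo, b_hi) + cm(a_hi, b_hi)) / 2 -
                   (cm(a_lo, b_lo) + cm(a_hi, b_lo)) / 2)
  data.frame(analyte = rownames(tab$values),
             p_age = p_of(f_age), p_diet = p_of(f_diet),
             p_interaction = p_of(f_int),
             dir_age = as.numeric(dir_age), dir_diet = as.numeric(dir_diet),
             row.names = NULL, stringsAsFactors = FALSE)
}
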