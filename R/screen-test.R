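# Negative-binomial enrichment statistics for sorted-population screens:
# a mean-variance trend fitted on control replicates, moment-matched NB
# tail probabilities per guide, and the classification rules applied
# downstream of the test.

#' Fit the mean-variance trend of a screen
#'
#' Models the per-replicate count variance as `sigma^2 = mu + k * mu^b`
#' (Poisson noise plus a power-law overdispersion term, the trend family
#' used by count-based screen testers). Per-guide means and sample
#' variances across the reference-role replicates are pooled into
#' equal-count bins ordered by mean; `(k, b)` are then obtained by
#' nonlinear least squares of `log(mu + k*mu^b)` against the log of the
#' bin-averaged variance. Bin averaging is what makes the fit usable at
#' 3 replicates: an individual 2-df sample variance is far too noisy (and
#' log-transforming it is biased), while bin means of many such variances
#' are unbiased for the trend. The guide-level regression of
#' `log(s^2 - mu)` on `log(mu)` over overdispersed guides supplies the
#' starting values.
#'
#' @param x a normalized [count_matrix()].
#' @param reference_role role whose replicates estimate the trend
#'   (default `"CXCR4neg"`).
#' @param n_bins number of equal-count bins (default 50, reduced
#'   automatically for small libraries).
#' @param exclude guide ids left out of the fit (e.g. low-coverage
#'   removals).
#' @return a `mean_var_model` list with `k`, `b`, `n_points` (guides
#'   used), `n_bins`, `r_squared` (on bin log-variances) and the
#'   binned profile.
#' @export
fit_mean_variance <- function(x, reference_role = "CXCR4neg",
                              n_bins = 50L, exclude = character(0)) {
  stopifnot(inherits(x, "count_matrix"))
  if (!x$normalized) stop("normalize the matrix before fitting")
  cols <- role_columns(x, reference_role)
  if (length(cols) < 2L)
    stop("variance undefined: need >= 2 replicates of role ",
         reference_role)
  m <- x$counts[!(rownames(x$counts) %in% exclude), cols, drop = FALSE]
  mu <- rowMeans(m)
  s2 <- rowSums((m - mu)^2) / (ncol(m) - 1L)
  keep <- mu > 0
  mu <- mu[keep]; s2 <- s2[keep]
  if (sum(s2 > mu) < 50L)
    stop("insufficient overdispersion signal: only ", sum(s2 > mu),
         " guides with s^2 > mu (need >= 50)")
  # starting values: guide-level log-log regression on overdispersed guides
  od <- s2 > mu
  init <- stats::lm(log(s2[od] - mu[od]) ~ log(mu[od]))
  k0 <- max(exp(stats::coef(init)[1]), 1e-8)
  b0 <- stats::coef(init)[2]
  # equal-count bins ordered by mean
  n_bins <- max(5L, min(n_bins, floor(length(mu) / 20)))
  ord <- order(mu)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bmu <- tapply(mu[ord], bin, mean)
  bs2 <- tapply(s2[ord], bin, mean)
  obj <- function(theta) {
    k <- exp(theta[1]); b <- theta[2]
    sum((log(bmu + k * bmu^b) - log(bs2))^2)
  }
  fit <- stats::optim(c(log(k0), b0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  k <- unname(exp(fit$par[1])); b <- unname(fit$par[2])
  pred <- log(bmu + k * bmu^b)
  r2 <- 1 - sum((log(bs2) - pred)^2) /
    max(sum((log(bs2) - mean(log(bs2)))^2), .Machine$double.eps)
  structure(list(k = k, b = b, n_points = length(mu), n_bins = n_bins,
                 r_squared = r2, reference_role = reference_role,
                 profile = data.frame(mean = as.numeric(bmu),
                                      variance = as.numeric(bs2))),
            class = "mean_var_model")
}

#' @export
print.mean_var_model <- function(x, ...) {
  cat(sprintf(
    "mean-variance trend: sigma^2 = mu + k*mu^b, k = %.4g, b = %.3f\n",
    x$k, x$b))
  cat(sprintf("  fitted on %d guides (%d bins, role %s), R^2 = %.3f\n",
              x$n_points, x$n_bins, x$reference_role, x$r_squared))
  invisible(x)
}

# one-sided NB tail probabilities for a replicate-mean statistic.
# The null is moment-matched to mean mu and variance
# (mu + k*mu^b) * (1/n_trt + 1/n_ctrl): the trend gives the
# per-replicate variance, and the scaling accounts for averaging over
# treatment replicates and for the control mean itself being an
# estimate. Tail convention: p_low = P(X <= floor(obs)),
# p_high = P(X >= ceiling(obs)), so both tails contain the observed
# point's mass and p_low + p_high >= 1.
nb_tails <- function(obs, mu, k, b, n_trt, n_ctrl) {
  scale <- 1 / n_trt + 1 / n_ctrl
  v <- (mu + k * mu^b) * scale
  p_low <- p_high <- rep(NA_real_, length(obs))
  zero <- mu <= 0
  if (any(zero)) {
    # degenerate null: any nonzero observation is maximally enriched
    p_low[zero] <- 1
    p_high[zero] <- ifelse(obs[zero] <= 0, 1, .Machine$double.xmin)
  }
  nz <- !zero
  over <- nz & v > mu
  if (any(over)) {
    size <- mu[over]^2 / (v[over] - mu[over])
    p_low[over] <- stats::pnbinom(floor(obs[over]), size = size,
                                  mu = mu[over])
    p_high[over] <- stats::pnbinom(ceiling(obs[over]) - 1, size = size,
                                   mu = mu[over], lower.tail = FALSE)
  }
  pois <- nz & v <= mu
  if (any(pois)) {
    lambda <- v[pois]  # variance-matched Poisson (v < mu only if scale < 1)
    p_low[pois] <- stats::ppois(floor(obs[pois] - mu[pois] + lambda),
                                lambda)
    p_high[pois] <- stats::ppois(ceiling(obs[pois] - mu[pois] + lambda) - 1,
                                 lambda, lower.tail = FALSE)
  }
  list(p_low = pmax(pmin(p_low, 1), .Machine$double.xmin),
       p_high = pmax(pmin(p_high, 1), .Machine$double.xmin))
}

#' Fit the sorted-population enrichment model of a screen
#'
#' The main fitting entry point. Applies the low-count filter, fits the
#' mean-variance trend on control replicates ([fit_mean_variance()]),
#' computes per-guide replicate LFCs and their median
#' ([compute_lfc()], numerator = treatment role), and assigns each guide
#' one-sided NB tail probabilities `p_low`/`p_high` for its mean
#' treatment abundance under a null centred on its mean control
#' abundance.
#'
#' @param x a normalized [count_matrix()].
#' @param treatment_role numerator population (default `"CXCR4pos"`).
#' @param control_role denominator/reference population (default
#'   `"CXCR4neg"`).
#' @param pseudocount LFC pseudocount (default 1).
#' @param low_count_threshold guides below this mean normalized count in
#'   either sorted role are flagged and excluded from the trend fit and
#'   from testing (set 0 to disable).
#' @param n_bins passed to [fit_mean_variance()].
#' @return an object of class `screen_nb` with components `model` (the
#'   `mean_var_model`), `table` (per-guide results: means, replicate and
#'   median LFCs, `p_low`, `p_high`, `low_count_removed`,
#'   `is_nontargeting`), and the call parameters.
#' @seealso [call_hits()], [collapse_to_sites()],
#'   [estimate_nontargeting_fpr()]
#' @export
screen_nb_test <- function(x, treatment_role = "CXCR4pos",
                           control_role = "CXCR4neg", pseudocount = 1,
                           low_count_threshold = 200, n_bins = 50L) {
  stopifnot(inherits(x, "count_matrix"))
  if (!x$normalized) stop("normalize the matrix before testing")
  filt <- if (low_count_threshold > 0)
    low_count_filter(x, roles = c(control_role, treatment_role),
                     threshold = low_count_threshold)
  else list(retained = rownames(x$counts), removed = character(0))
  model <- fit_mean_variance(x, reference_role = control_role,
                             n_bins = n_bins, exclude = filt$removed)
  tcols <- role_columns(x, treatment_role)
  ccols <- role_columns(x, control_role)
  mu_t <- rowMeans(x$counts[, tcols, drop = FALSE])
  mu_c <- rowMeans(x$counts[, ccols, drop = FALSE])
  tails <- nb_tails(mu_t, mu_c, model$k, model$b,
                    n_trt = length(tcols), n_ctrl = length(ccols))
  lfc <- compute_lfc(x, treatment_role, control_role, pseudocount)
  tab <- data.frame(
    sgRNA_id = rownames(x$counts),
    gene = x$gene, site_id = x$site_id,
    is_nontargeting = x$nontargeting,
    mean_ctrl = mu_c, mean_trt = mu_t,
    lfc[, grep("^lfc_r", names(lfc)), drop = FALSE],
    median_lfc = lfc$median_lfc,
    p_low = tails$p_low, p_high = tails$p_high,
    low_count_removed = rownames(x$counts) %in% filt$removed,
    stringsAsFactors = FALSE, row.names = NULL)
  tab$p_low[tab$low_count_removed] <- NA_real_
  tab$p_high[tab$low_count_removed] <- NA_real_
  structure(list(model = model, table = tab,
                 treatment_role = treatment_role,
                 control_role = control_role,
                 n_trt = length(tcols), n_ctrl = length(ccols),
                 pseudocount = pseudocount,
                 low_count_threshold = low_count_threshold),
            class = "screen_nb")
}

#' @export
print.screen_nb <- function(x, ...) {
  cat(sprintf("screen_nb fit: %s vs %s, %d guides (%d removed low-count)\n",
              x$treatment_role, x$control_role, nrow(x$table),
              sum(x$table$low_count_removed)))
  print(x$model)
  invisible(x)
}

#' @export
summary.screen_nb <- function(object, p_thresh = 0.05,
                              lfc_relaxed = 0.58, ...) {
  tab <- object$table[!object$table$low_count_removed, ]
  out <- list(
    fit = object,
    n_tested = nrow(tab),
    n_sig_high = sum(tab$p_high < p_thresh & tab$median_lfc > lfc_relaxed,
                     na.rm = TRUE),
    n_sig_low = sum(tab$p_low < p_thresh & tab$median_lfc < -lfc_relaxed,
                    na.rm = TRUE),
    lfc_quartiles = stats::quantile(tab$median_lfc, c(.25, .5, .75)),
    p_thresh = p_thresh, lfc_relaxed = lfc_relaxed)
  class(out) <- "summary.screen_nb"
  out
}

#' @export
print.summary.screen_nb <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  tested: %d guides; at p < %.2f and |median LFC| > %.2f:\n",
              x$n_tested, x$p_thresh, x$lfc_relaxed))
  cat(sprintf("    enriched in %s: %d; enriched in %s: %d\n",
              x$fit$treatment_role, x$n_sig_high,
              x$fit$control_role, x$n_sig_low))
  cat("  median LFC quartiles: ",
      paste(sprintf("%.2f", x$lfc_quartiles), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.screen_nb <- function(object, ...) {
  c(k = object$model$k, b = object$model$b)
}

#' @export
plot.screen_nb <- function(x, which = c("meanvar", "volcano"), ...) {
  which <- match.arg(which)
  if (which == "meanvar") {
    pr <- x$model$profile
    plot(pr$mean, pr$variance, log = "xy",
         xlab = "mean normalized count", ylab = "variance",
         main = "mean-variance trend", pch = 16, col = "grey40", ...)
    mu <- exp(seq(log(min(pr$mean)), log(max(pr$mean)), length.out = 200))
    graphics::lines(mu, mu + x$model$k * mu^x$model$b, col = "red3", lwd = 2)
    graphics::lines(mu, mu, lty = 2, col = "grey60")
  } else {
    tab <- x$table[!x$table$low_count_removed, ]
    p <- pmin(tab$p_low, tab$p_high)
    plot(tab$median_lfc, -log10(p),
         xlab = sprintf("median LFC (%s/%s)", x$treatment_role,
                        x$control_role),
         ylab = "-log10 min(p_low, p_high)", pch = 16,
         col = ifelse(tab$is_nontargeting, "grey70", "grey25"),
         main = "per-guide enrichment", ...)
    graphics::abline(v = c(-0.58, 0.58), h = -log10(0.05), lty = 3)
  }
  invisible(x)
}

#' Simulate null screens from a fitted mean-variance trend
#'
#' Draws `nsim` guide x sample count matrices with every guide at its
#' observed control mean in all samples and NB noise following the
#' fitted trend — the parametric null of the fit, useful for checking
#' test calibration.
#'
#' @param object a `screen_nb` fit.
#' @param nsim number of simulated screens.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` raw count matrices (guides x (n_ctrl + n_trt)).
#' @export
simulate.screen_nb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- object$table[!object$table$low_count_removed, ]
  mu <- tab$mean_ctrl
  k <- object$model$k; b <- object$model$b
  n_col <- object$n_ctrl + object$n_trt
  lapply(seq_len(nsim), function(i) {
    m <- vapply(seq_len(n_col), function(j)
      rnbinom_meanvar(length(mu), mu, mu + k * mu^b), numeric(length(mu)))
    rownames(m) <- tab$sgRNA_id
    colnames(m) <- c(paste0(object$control_role, "_r",
                            seq_len(object$n_ctrl)),
                     paste0(object$treatment_role, "_r",
                            seq_len(object$n_trt)))
    m
  })
}

# NB draw parameterized by mean and variance (Poisson when v <= mu)
rnbinom_meanvar <- function(n, mu, v) {
  out <- numeric(n)
  pois <- v <= mu | mu <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), pmax(mu[pois], 0))
  if (any(!pois)) {
    size <- mu[!pois]^2 / (v[!pois] - mu[!pois])
    out[!pois] <- stats::rnbinom(sum(!pois), size = size, mu = mu[!pois])
  }
  out
}

#' Call significantly enriched guides
#'
#' Applies the paper-style joint rule to a `screen_nb` fit:
#' `hit_CXCR4pos` iff `p_high < p_thresh` and `median_lfc > lfc_relaxed`;
#' `hit_CXCR4neg` iff `p_low < p_thresh` and `median_lfc < -lfc_relaxed`;
#' `highconf_*` use `lfc_stringent` instead. Guides predicted to induce
#' missense mutations are excluded when `exclude_missense = TRUE`
#' (they may act through the amino-acid change rather than the methyl
#' mark); non-targeting guides and low-count removals are flagged but
#' never counted as hits.
#'
#' @param fit a [screen_nb_test()] result.
#' @param annotation optional consequence annotation joined by
#'   `sgRNA_id` (needs `region`/`coding_effect`, e.g. from
#'   [predict_edit_consequence()] or an annotated library table).
#' @param p_thresh one-sided p threshold (default 0.05).
#' @param lfc_relaxed relaxed |median LFC| floor (default 0.58, i.e.
#'   1.5-fold).
#' @param lfc_stringent stringent |median LFC| floor (default 1.0).
#' @param exclude_missense apply the missense filter (default TRUE).
#' @return data.frame of per-guide results with logical flag columns
#'   `hit_CXCR4pos`, `hit_CXCR4neg`, `highconf_CXCR4pos`,
#'   `highconf_CXCR4neg`, `missense_excluded`, `low_count_removed`.
#' @export
call_hits <- function(fit, annotation = NULL, p_thresh = 0.05,
                      lfc_relaxed = 0.58, lfc_stringent = 1.0,
                      exclude_missense = TRUE) {
  stopifnot(inherits(fit, "screen_nb"))
  if (p_thresh <= 0 || lfc_relaxed <= 0 || lfc_stringent <= 0)
    stop("thresholds must be > 0")
  res <- fit$table
  res$region <- NA_character_
  res$coding_effect <- NA_character_
  if (!is.null(annotation)) {
    i <- match(res$sgRNA_id, annotation$sgRNA_id)
    res$region <- annotation$region[i]
    res$coding_effect <- annotation$coding_effect[i]
  }
  res$missense_excluded <- exclude_missense &
    !is.na(res$coding_effect) & res$coding_effect == "missense"
  eligible <- !res$low_count_removed & !res$is_nontargeting &
    !res$missense_excluded
  res$hit_CXCR4pos <- eligible & !is.na(res$p_high) &
    res$p_high < p_thresh & res$median_lfc > lfc_relaxed
  res$hit_CXCR4neg <- eligible & !is.na(res$p_low) &
    res$p_low < p_thresh & res$median_lfc < -lfc_relaxed
  res$highconf_CXCR4pos <- res$hit_CXCR4pos & res$median_lfc > lfc_stringent
  res$highconf_CXCR4neg <- res$hit_CXCR4neg & res$median_lfc < -lfc_stringent
  attr(res, "thresholds") <- c(p = p_thresh, lfc_relaxed = lfc_relaxed,
                               lfc_stringent = lfc_stringent)
  res
}

#' Collapse guide-level hits to m6A sites
#'
#' A site is enriched in a direction iff at least one of its guides
#' carries that direction's hit flag. Guides without a site id
#' (non-targeting, stop controls) are ignored.
#'
#' @param results a [call_hits()] data.frame.
#' @param stringent use the `highconf_*` flags instead of `hit_*`.
#' @return data.frame with one row per direction: `direction`,
#'   `n_sites`, `n_sgrnas`, plus a `sites` attribute listing per-site
#'   membership.
#' @export
collapse_to_sites <- function(results, stringent = FALSE) {
  flags <- if (stringent) c("highconf_CXCR4neg", "highconf_CXCR4pos")
  else c("hit_CXCR4neg", "hit_CXCR4pos")
  keep <- !is.na(results$site_id)
  out <- do.call(rbind, lapply(seq_along(flags), function(i) {
    hit <- keep & results[[flags[i]]]
    data.frame(direction = c("CXCR4neg", "CXCR4pos")[i],
               n_sites = length(unique(results$site_id[hit])),
               n_sgrnas = sum(hit), stringsAsFactors = FALSE)
  }))
  attr(out, "sites") <- list(
    CXCR4neg = unique(results$site_id[keep & results[[flags[1]]]]),
    CXCR4pos = unique(results$site_id[keep & results[[flags[2]]]]))
  out
}

#' Empirical false-positive rate from non-targeting guides
#'
#' Applies the direction-specific joint p/LFC rule to the non-targeting
#' guides only (no missense logic: they have no genomic target) and
#' returns the per-direction fractions called.
#'
#' @param fit_or_results a `screen_nb` fit or a [call_hits()] data.frame.
#' @param p_thresh,lfc_thresh the rule's thresholds.
#' @return named numeric: `fpr_neg`, `fpr_pos` (fractions in `[0, 1]`).
#' @export
estimate_nontargeting_fpr <- function(fit_or_results, p_thresh = 0.05,
                                      lfc_thresh = 0.58) {
  tab <- if (inherits(fit_or_results, "screen_nb")) fit_or_results$table
  else fit_or_results
  ntc <- tab[tab$is_nontargeting & !tab$low_count_removed, ]
  if (nrow(ntc) == 0L) stop("no non-targeting guides present")
  c(fpr_neg = mean(ntc$p_low < p_thresh & ntc$median_lfc < -lfc_thresh,
                   na.rm = TRUE),
    fpr_pos = mean(ntc$p_high < p_thresh & ntc$median_lfc > lfc_thresh,
                   na.rm = TRUE))
}

#' Classify guides as toxic or proliferative against a baseline
#'
#' Compares the undifferentiated baseline with each sorted population
#' using the replicate-median `log2(baseline / population)`: a guide is
#' `toxic` iff that median exceeds `lfc_cut` against BOTH populations
#' (over-represented in the starting cells, i.e. its edit depletes
#' cells of either fate), and `proliferative` iff it is below
#' `-lfc_cut` against both.
#'
#' @param x a normalized [count_matrix()] containing the baseline role.
#' @param baseline_role baseline sample role (default `"baseline_d0"`).
#' @param population_roles the two sorted roles.
#' @param lfc_cut |median LFC| cut (default 1, i.e. 2-fold).
#' @param pseudocount LFC pseudocount.
#' @return data.frame with `sgRNA_id`, per-population median LFCs,
#'   logical `toxic` and `proliferative`.
#' @export
classify_baseline_effects <- function(x, baseline_role = "baseline_d0",
                                      population_roles = c("CXCR4neg",
                                                           "CXCR4pos"),
                                      lfc_cut = 1.0, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (!baseline_role %in% x$samples$role)
    stop("missing baseline role '", baseline_role, "'")
  lfcs <- lapply(population_roles, function(role)
    compute_lfc(x, baseline_role, role, pseudocount)$median_lfc)
  names(lfcs) <- population_roles
  m <- do.call(cbind, lfcs)
  out <- data.frame(sgRNA_id = rownames(x$counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (role in population_roles)
    out[[paste0("lfc_vs_", role)]] <- m[, role]
  out$toxic <- apply(m > lfc_cut, 1, all)
  out$proliferative <- apply(m < -lfc_cut, 1, all)
  out
}

#' Longitudinal depletion/enrichment calls for a proliferation screen
#'
#' For a two-timepoint (e.g. day 0 vs day 30) screen: per-guide LFC of
#' normalized counts between the timepoints, thresholded at `|LFC| >
#' lfc_cut`. With replicated timepoints the replicate-median LFC is
#' used.
#'
#' @param x a normalized [count_matrix()].
#' @param day0_role,dayN_role the two timepoint roles.
#' @param lfc_cut threshold (default 1).
#' @param pseudocount LFC pseudocount.
#' @return data.frame with `sgRNA_id`, `lfc`, logical `depleted`
#'   (`lfc < -lfc_cut`) and `enriched` (`lfc > lfc_cut`).
#' @export
be3_longitudinal_calls <- function(x, day0_role = "timepoint_d0",
                                   dayN_role = "timepoint_d30",
                                   lfc_cut = 1.0, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  for (role in c(day0_role, dayN_role))
    if (!role %in% x$samples$role) stop("missing timepoint role '", role, "'")
  lfc <- compute_lfc(x, dayN_role, day0_role, pseudocount)
  data.frame(sgRNA_id = lfc$sgRNA_id, lfc = lfc$median_lfc,
             depleted = lfc$median_lfc < -lfc_cut,
             enriched = lfc$median_lfc > lfc_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
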