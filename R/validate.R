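#' Stratified review sampling plan
#'
#' Mirrors the validation workflow: per cancer group, a consensus batch
#' reviewed jointly (default 12), then joint independent batches (default 20
#' at a time) drawn from a group sample (default 100) until the agreement
#' rule is met, then the remainder split between reviewers; plus up to
#' `supplemental` extra records per under-represented stratum to sharpen
#' stratum-level estimates.
#'
#' @param per_group records sampled per cancer group.
#' @param consensus_batch jointly reviewed consensus batch size.
#' @param joint_batch batch size for the paired-review (kappa) phase.
#' @param supplemental max extra records per under-sampled stratum.
#' @return a `digephen_sampling_plan`.
#' @export
sampling_plan <- function(per_group = 100L, consensus_batch = 12L,
                          joint_batch = 20L, supplemental = 40L) {
  structure(list(per_group = as.integer(per_group),
                 consensus_batch = as.integer(consensus_batch),
                 joint_batch = as.integer(joint_batch),
                 supplemental = as.integer(supplemental)),
            class = "digephen_sampling_plan")
}

#' Draw the stratified review sample
#'
#' Per cancer group: `per_group` cases drawn without replacement,
#' proportionally across strata (largest-remainder rounding), then up to
#' `supplemental` additional cases per stratum that the proportional draw
#' left thin. Requests beyond a stratum's population are clipped with a
#' warning. Stratum shares of the full case pool are recorded for PPV
#' weighting. Reproducible given `seed`.
#'
#' @param cases PotentialCase table from [find_cases()].
#' @param plan a [sampling_plan()].
#' @param seed integer seed.
#' @return list: `sample` (case rows plus `review_phase` =
#'   consensus/joint/independent), `pool_weights` (per cancer x stratum
#'   share of the full pool).
#' @export
draw_sample <- function(cases, plan = sampling_plan(), seed = 1L) {
  set.seed(derive_seed(seed, "draw_sample"))
  out <- list(); w <- list()
  for (ct in intersect(CANCER_TYPES, unique(cases$cancer_type))) {
    pool <- cases[cases$cancer_type == ct, , drop = FALSE]
    if (plan$per_group > nrow(pool))
      warn_digephen("cancer group %s has only %d cases; requested %d, drawing all",
                    ct, nrow(pool), plan$per_group)
    n_str <- table(factor(pool$stratum, STRATA))
    if (any(n_str == 0))
      warn_digephen("empty stratum(s) for %s: %s (zero draw)", ct,
                    paste(STRATA[n_str == 0], collapse = ", "))
    share <- as.numeric(n_str) / nrow(pool)
    w[[ct]] <- data.frame(cancer_type = ct, stratum = STRATA,
                          pool_n = as.integer(n_str), pool_share = share,
                          stringsAsFactors = FALSE)
    # proportional allocation of the group sample, largest remainders
    target <- share * min(plan$per_group, nrow(pool))
    base <- floor(target)
    rem <- order(target - base, decreasing = TRUE)
    extra <- sum(round(sum(target)) - sum(base))
    alloc <- base
    if (extra > 0) alloc[rem[seq_len(extra)]] <- alloc[rem[seq_len(extra)]] + 1
    # supplemental top-up for thin strata
    topup <- pmin(pmax(plan$supplemental - alloc, 0), as.integer(n_str) - alloc)
    alloc <- pmin(alloc + pmax(topup, 0), as.integer(n_str))
    picked <- do.call(rbind, lapply(seq_along(STRATA), function(i) {
      s_pool <- pool[pool$stratum == STRATA[i], , drop = FALSE]
      k <- alloc[i]
      if (k > nrow(s_pool)) {
        warn_digephen("stratum %s/%s has only %d cases; requested %d",
                      ct, STRATA[i], nrow(s_pool), k)
        k <- nrow(s_pool)
      }
      if (!k) return(NULL)
      s_pool[sample.int(nrow(s_pool), k), , drop = FALSE]
    }))
    if (is.null(picked)) next
    picked <- picked[sample.int(nrow(picked)), , drop = FALSE]
    n <- nrow(picked)
    phase <- rep("independent", n)
    phase[seq_len(min(plan$consensus_batch, n))] <- "consensus"
    if (n > plan$consensus_batch)
      phase[(plan$consensus_batch + 1):min(plan$consensus_batch +
                                             plan$joint_batch, n)] <- "joint"
    picked$review_phase <- phase
    out[[ct]] <- picked
  }
  sample <- do.call(rbind, out)
  rownames(sample) <- NULL
  list(sample = sample, pool_weights = do.call(rbind, w))
}

#' Linearly weighted Cohen's kappa
#'
#' Chance-corrected inter-rater agreement over ordered categories with
#' linear disagreement weights `w_ij = 1 - |i - j| / (k - 1)`. The category
#' order materially affects the statistic, so it must be supplied
#' explicitly.
#'
#' @param ratings_a,ratings_b paired rating vectors (same length).
#' @param categories ordered category levels.
#' @return the weighted kappa point estimate.
#' @export
#' @examples
#' cohen_kappa_linear(c("valid", "valid", "non_valid"),
#'                    c("valid", "valid", "non_valid"),
#'                    categories = c("valid", "inconclusive",
#'                                   "non_valid", "unsupported"))
cohen_kappa_linear <- function(ratings_a, ratings_b,
                               categories = ADJ_CATEGORIES) {
  stopifnot(length(ratings_a) == length(ratings_b))
  if (length(ratings_a) < 2L)
    stop_digephen("need at least 2 paired ratings")
  a <- factor(ratings_a, levels = categories)
  b <- factor(ratings_b, levels = categories)
  if (anyNA(a) || anyNA(b))
    stop_digephen("ratings outside the supplied category set")
  k <- length(categories)
  tab <- table(a, b) / length(a)
  idx <- seq_len(k)
  w <- 1 - abs(outer(idx, idx, "-")) / (k - 1)
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - pe) < 1e-12)
    stop_digephen("kappa undefined: degenerate marginals")
  (po - pe) / (1 - pe)
}

#' Binomial proportion confidence interval
#'
#' `wald` is the default because it reproduces the intervals conventionally
#' printed with validation PPVs; `clopper_pearson` (exact) and `wilson` are
#' available for small samples and boundary proportions, where Wald
#' degenerates.
#'
#' @param p_hat observed proportion.
#' @param n denominator.
#' @param method `"wald"`, `"clopper_pearson"` or `"wilson"`.
#' @param conf confidence level.
#' @return numeric `c(low, high)`, clipped to `[0, 1]`.
#' @export
#' @examples
#' proportion_ci(0.924, 760)               # 0.905, 0.943
#' proportion_ci(1, 30, "clopper_pearson") # non-degenerate lower bound
proportion_ci <- function(p_hat, n,
                          method = c("wald", "clopper_pearson", "wilson"),
                          conf = 0.95) {
  method <- match.arg(method)
  stopifnot(n >= 1, p_hat >= 0, p_hat <= 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p_hat * (1 - p_hat) / n)
    return(pmin(pmax(c(p_hat - half, p_hat + half), 0), 1))
  }
  x <- round(p_hat * n)
  if (method == "clopper_pearson") {
    lo <- if (x == 0) 0 else stats::qbeta((1 - conf) / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - (1 - conf) / 2, x + 1, n - x)
    return(c(lo, hi))
  }
  # wilson
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  pmin(pmax(c(centre - half, centre + half), 0), 1)
}

ppv_estimate <- function(scope, n_evaluated, n_valid, ci_method,
                         unsupported_handling, conf = 0.95) {
  if (n_evaluated == 0) {
    return(data.frame(scope = scope, n_evaluated = 0L, n_valid = 0L,
                      ppv = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      ci_method = ci_method,
                      unsupported_handling = unsupported_handling,
                      stringsAsFactors = FALSE))
  }
  p <- n_valid / n_evaluated
  ci <- proportion_ci(p, n_evaluated, ci_method, conf)
  data.frame(scope = scope, n_evaluated = as.integer(n_evaluated),
             n_valid = as.integer(n_valid), ppv = p, ci_low = ci[1],
             ci_high = ci[2], ci_method = ci_method,
             unsupported_handling = unsupported_handling,
             stringsAsFactors = FALSE)
}

#' Positive predictive value of an adjudicated case set
#'
#' Main analysis: inconclusive cases count as non-valid and unsupported
#' cases are dropped from both numerator and denominator, so
#' PPV = valid / (valid + non_valid + inconclusive). Sensitivity scenarios
#' instead keep unsupported cases and count them as valid
#' (`"as_valid"`) or non-valid (`"as_nonvalid"`).
#'
#' @param adjudications data frame with a final `category` column over
#'   `valid`, `inconclusive`, `non_valid`, `unsupported`.
#' @param scope label stored in the estimate.
#' @param unsupported_handling `"excluded"` (main), `"as_valid"`,
#'   `"as_nonvalid"`.
#' @param ci_method passed to [proportion_ci()].
#' @param conf confidence level.
#' @return a one-row PPVEstimate data frame.
#' @export
ppv <- function(adjudications, scope = "all",
                unsupported_handling = c("excluded", "as_valid",
                                         "as_nonvalid"),
                ci_method = "wald", conf = 0.95) {
  unsupported_handling <- match.arg(unsupported_handling)
  cat <- adjudications$category
  bad <- setdiff(unique(cat), ADJ_CATEGORIES)
  if (length(bad))
    stop_digephen("unknown adjudication category: %s",
                  paste(bad, collapse = ", "))
  n_valid <- sum(cat == "valid")
  n_unsup <- sum(cat == "unsupported")
  n_other <- sum(cat %in% c("non_valid", "inconclusive"))
  denom <- switch(unsupported_handling,
                  excluded = n_valid + n_other,
                  as_valid = n_valid + n_other + n_unsup,
                  as_nonvalid = n_valid + n_other + n_unsup)
  num <- switch(unsupported_handling,
                excluded = n_valid,
                as_valid = n_valid + n_unsup,
                as_nonvalid = n_valid)
  ppv_estimate(scope, denom, num, ci_method, unsupported_handling, conf)
}

#' Stratum-weighted mean PPV
#'
#' The group-level PPV is the mean of the stratum PPVs weighted by each
#' stratum's share of the *full* case pool (not of the review sample). The
#' default CI applies [proportion_ci()] to the weighted point with
#' effective n equal to the total evaluated count; `ci_method = "weighted"`
#' gives the delta-method variance-weighted alternative
#' `var = sum(w^2 p(1-p)/n)`.
#'
#' @param stratum_estimates PPVEstimate rows (one per non-empty stratum).
#' @param weights stratum shares of the full pool; must sum to 1 (+-1e-9)
#'   over the supplied strata.
#' @param scope label for the combined estimate.
#' @param ci_method `"wald"`, `"clopper_pearson"`, `"wilson"` or
#'   `"weighted"`.
#' @param conf confidence level.
#' @return a one-row PPVEstimate data frame.
#' @export
weighted_mean_ppv <- function(stratum_estimates, weights, scope = "overall",
                              ci_method = "wald", conf = 0.95) {
  keep <- !is.na(stratum_estimates$ppv)
  est <- stratum_estimates[keep, , drop = FALSE]
  weights <- weights[keep]
  if (abs(sum(weights) - 1) > 1e-9)
    stop_digephen("stratum weights must sum to 1 (got %.6f)", sum(weights))
  point <- sum(weights * est$ppv)
  n_eff <- sum(est$n_evaluated)
  if (ci_method == "weighted") {
    se <- sqrt(sum(weights^2 * est$ppv * (1 - est$ppv) / est$n_evaluated))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- pmin(pmax(c(point - z * se, point + z * se), 0), 1)
    return(data.frame(scope = scope, n_evaluated = as.integer(n_eff),
                      n_valid = as.integer(round(point * n_eff)),
                      ppv = point, ci_low = ci[1], ci_high = ci[2],
                      ci_method = "weighted",
                      unsupported_handling = est$unsupported_handling[1],
                      stringsAsFactors = FALSE))
  }
  ci <- proportion_ci(point, n_eff, ci_method, conf)
  out <- ppv_estimate(scope, n_eff, round(point * n_eff), ci_method,
                      est$unsupported_handling[1], conf)
  out$ppv <- point; out$ci_low <- ci[1]; out$ci_high <- ci[2]
  out
}

#' Sex-stratified PPVs
#'
#' Splits the adjudicated set by patient sex to check for differential
#' record quality. A sex with no evaluated cases yields an `NA`-flagged
#' estimate.
#'
#' @inheritParams ppv
#' @param sex_map named character vector `case_id -> sex`, or a data frame
#'   with `case_id` and `sex`.
#' @return PPVEstimate data frame, one row per sex.
#' @export
ppv_by_sex <- function(adjudications, sex_map,
                       unsupported_handling = "excluded",
                       ci_method = "wald", conf = 0.95) {
  if (is.data.frame(sex_map))
    sex_map <- stats::setNames(sex_map$sex, sex_map$case_id)
  sex <- unname(sex_map[as.character(adjudications$case_id)])
  do.call(rbind, lapply(c("male", "female"), function(s) {
    ppv(adjudications[!is.na(sex) & sex == s, , drop = FALSE],
        scope = s, unsupported_handling = unsupported_handling,
        ci_method = ci_method, conf = conf)
  }))
}

#' Per-cancer, per-stratum validation report
#'
#' Produces the standard validation summary: one PPV row per cancer x
#' stratum, a pool-weighted overall row per cancer, and a global weighted
#' row, in main-analysis handling (unsupported excluded) or any sensitivity
#' scenario.
#'
#' @param adjudications final adjudications with `case_id` and `category`.
#' @param sampled the `sample` table from [draw_sample()] (needs `case_id`
#'   created as `patient_id`, plus `cancer_type`, `stratum`).
#' @param pool_weights the `pool_weights` table from [draw_sample()].
#' @inheritParams ppv
#' @return PPVEstimate data frame.
#' @export
validation_report <- function(adjudications, sampled, pool_weights,
                              unsupported_handling = "excluded",
                              ci_method = "wald", conf = 0.95) {
  adj <- merge(adjudications,
               sampled[c("case_id", "cancer_type", "stratum")],
               by = "case_id")
  rows <- list(); overall_parts <- list()
  for (ct in intersect(CANCER_TYPES, unique(adj$cancer_type))) {
    strata_rows <- list()
    for (s in STRATA) {
      sub <- adj[adj$cancer_type == ct & adj$stratum == s, , drop = FALSE]
      strata_rows[[s]] <- ppv(sub, scope = paste(ct, s, sep = "/"),
                              unsupported_handling = unsupported_handling,
                              ci_method = ci_method, conf = conf)
    }
    st <- do.call(rbind, strata_rows)
    pw <- pool_weights[pool_weights$cancer_type == ct, , drop = FALSE]
    wts <- pw$pool_share[match(STRATA, pw$stratum)]
    keep <- !is.na(st$ppv) & wts > 0
    wmean <- weighted_mean_ppv(st[keep, , drop = FALSE],
                               wts[keep] / sum(wts[keep]),
                               scope = paste0(ct, "/weighted_mean"),
                               ci_method = ci_method, conf = conf)
    rows[[ct]] <- rbind(st, wmean)
    overall_parts[[ct]] <- list(est = wmean, n_pool = sum(pw$pool_n))
  }
  # global weighted mean: cancer-group means weighted by pool size
  n_pool <- vapply(overall_parts, `[[`, numeric(1), "n_pool")
  ests <- do.call(rbind, lapply(overall_parts, `[[`, "est"))
  global <- weighted_mean_ppv(ests, n_pool / sum(n_pool),
                              scope = "overall/weighted_mean",
                              ci_method = ci_method, conf = conf)
  out <- rbind(do.call(rbind, rows), global)
  rownames(out) <- NULL
  out
}
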