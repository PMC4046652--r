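#' Normalized theta transform of two-channel intensities
#'
#' `theta = (2/pi) * atan(Cy5/Cy3)`, so a homozygote for allele A (all
#' signal in Cy3) sits at theta 0, a homozygote for allele B at theta 1,
#' and a balanced heterozygote at 0.5. `normR = Cy3 + Cy5` is the total
#' signal. Theta is scale-invariant and monotone in Cy5/Cy3. Points with
#' no signal in either channel get `NA` theta and count against the call
#' rate downstream.
#'
#' @param cy3,cy5 Non-negative channel intensities (vectorized).
#' @return data.table with `theta` and `normR`.
#' @export
theta_transform <- function(cy3, cy5) {
  if (any(cy3 < 0 | cy5 < 0)) stop("intensities must be non-negative")
  theta <- (2 / pi) * atan2(cy5, cy3)
  theta[cy3 == 0 & cy5 == 0] <- NA_real_
  data.table::data.table(theta = theta, normR = cy3 + cy5)
}

#' Fit a 1-D cluster model to theta values
#'
#' For each candidate k up to `k_max`, an equal-variance Gaussian mixture
#' is fitted by EM initialized from the exact 1-D k-means partition
#' (computed by dynamic programming over the sorted values, so the fit is
#' fully deterministic: no random restarts). k is selected by BIC;
#' ties resolve toward smaller k (parsimony, mirroring conservative manual
#' re-clustering). The shared variance is floored at 1e-6 so noise-free
#' groups remain well-posed; candidate k values larger than the number of
#' distinct theta values, or whose fit leaves a component empty under
#' maximum-responsibility assignment, are skipped. Fits whose adjacent
#' centers lie closer than `min_separation` are also skipped: two theta
#' groups closer than the assay's resolving power are one genotype cluster,
#' not two (the theta noise is mildly heteroscedastic - the heterozygote
#' cluster is wider than the homozygote clusters - and a shared-variance
#' fit would otherwise split it).
#'
#' @param theta Numeric theta values (NAs dropped).
#' @param k_max Largest cluster count considered (default 6).
#' @param min_separation Smallest admissible gap between adjacent cluster
#'   centers (default 0.12; genotype clusters of a working assay sit at
#'   least ~0.19 apart in theta).
#' @param min_occupancy Smallest admissible cluster share (default 0.05 of
#'   the points, never fewer than 3): a genotype group in a 1:1 or 1:2:1
#'   segregating design holds a non-negligible share of the samples,
#'   whereas heavy-tailed intensity noise occasionally offers a tiny
#'   spurious component.
#' @return An object of class `cluster_model`: `k`, `centers` (ascending),
#'   `assignment` (per input value, NA where theta was NA), `scores`
#'   (per-k BIC, lower is better).
#' @export
fit_clusters <- function(theta, k_max = 6L, min_separation = 0.12,
                         min_occupancy = 0.05) {
  keep <- !is.na(theta)
  x <- theta[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 points to fit clusters")
  sigma2_floor <- 1e-6
  scores <- rep(NA_real_, k_max)
  fits <- vector("list", k_max)
  xs <- sort(x)
  all_init <- kmeans_1d(xs, min(k_max, n))
  for (k in seq_len(min(k_max, n))) {
    if (k > length(unique(x))) next
    init <- all_init[[k]]
    # admissibility pre-filter on the optimal hard partition: same
    # occupancy and separation rules the final fit must satisfy
    if (min(init$sizes) < max(3L, ceiling(min_occupancy * n))) next
    if (k > 1L && min(diff(init$centers)) < min_separation) next
    mu <- init$centers
    w <- init$sizes / n
    sigma2 <- max(init$wss / n, sigma2_floor)
    ll_old <- -Inf
    for (it in seq_len(30L)) {
      dev <- outer(x, mu, "-")
      dens <- stats::dnorm(dev, 0, sqrt(sigma2)) *
        rep(w, each = n)
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      if (any(nk < 1e-12)) break
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sigma2 <- max(sum(resp * (x - rep(mu, each = n))^2) / n, sigma2_floor)
      if (is.finite(ll) && abs(ll - ll_old) < 1e-8) break
      ll_old <- ll
    }
    assign <- max.col(resp, ties.method = "first")
    if (min(tabulate(assign, nbins = k)) < max(3L, ceiling(min_occupancy * n)))
      next
    if (k > 1L && min(diff(sort(mu))) < min_separation) next
    scores[k] <- -2 * ll + 2 * k * log(n)   # k means, k-1 weights, 1 variance
    fits[[k]] <- list(mu = mu, assign = assign)
  }
  if (all(is.na(scores))) stop("no valid cluster fit")
  best_k <- which(scores <= min(scores, na.rm = TRUE) + 1e-9)[1L]
  fit <- fits[[best_k]]
  o <- order(fit$mu)
  relabel <- match(seq_along(fit$mu), o)
  assignment <- rep(NA_integer_, length(theta))
  assignment[keep] <- relabel[fit$assign]
  structure(list(k = best_k, centers = fit$mu[o],
                 assignment = assignment, scores = scores),
            class = "cluster_model")
}

# Exact 1-D k-means on sorted values via dynamic programming: the
# globally WSS-optimal partition into m contiguous segments, for every
# m up to k_max in one pass. O(k_max n^2), ample at assay scale. Used as
# the deterministic EM initializer.
kmeans_1d <- function(xs, k_max) {
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {
    # WSS of xs[i..j], vectorized over i
    s <- cs[j + 1L] - cs[i]
    s2 <- cs2[j + 1L] - cs2[i]
    pmax(s2 - s^2 / (j - i + 1L), 0)
  }
  dp <- matrix(Inf, k_max, n)
  cut_at <- matrix(0L, k_max, n)
  dp[1L, ] <- seg_cost(rep(1L, n), seq_len(n))
  if (k_max > 1L) for (m in 2:k_max) {
    for (j in m:n) {
      i <- m:j
      v <- dp[m - 1L, i - 1L] + seg_cost(i, j)
      arg <- which.min(v)
      dp[m, j] <- v[arg]
      cut_at[m, j] <- i[arg]
    }
  }
  lapply(seq_len(k_max), function(k) {
    starts <- integer(k)
    ends <- integer(k)
    j <- n
    for (m in k:1L) {
      i <- if (m == 1L) 1L else cut_at[m, j]
      starts[m] <- i
      ends[m] <- j
      j <- i - 1L
    }
    list(centers = vapply(seq_len(k), function(m)
           mean(xs[starts[m]:ends[m]]), numeric(1L)),
         sizes = ends - starts + 1L,
         wss = dp[k, n])
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("1-D cluster model: k =", x$k, "centers at",
      paste(sprintf("%.3f", x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Call genotypes from a fitted cluster model
#'
#' A point is a no-call when its total intensity falls below `min_normR`,
#' its theta is undefined, or it sits further than `max_dist` from the
#' nearest cluster center; otherwise it is called as the nearest cluster
#' (clusters labelled 1..k by ascending theta center).
#'
#' @param model A `cluster_model`.
#' @param theta,normR Per-sample transformed intensities.
#' @param min_normR Total-intensity floor (default 1500).
#' @param max_dist No-call distance from the nearest center (default 0.1).
#' @return List: `call` (integer cluster or NA), `call_rate`.
#' @export
call_gg_genotypes <- function(model, theta, normR, min_normR = 1500,
                              max_dist = 0.1) {
  th <- ifelse(is.na(theta), model$centers[1L], theta)
  d <- abs(outer(th, model$centers, "-"))
  nearest <- max.col(-d, ties.method = "first")
  mind <- d[cbind(seq_along(th), nearest)]
  call <- ifelse(is.na(theta) | normR < min_normR | mind > max_dist,
                 NA_integer_, nearest)
  list(call = call, call_rate = mean(!is.na(call)))
}

#' Drop samples whose across-assay call rate falls below a floor
#'
#' @param calls data.table with `sample`, `assay`, `call`.
#' @param min_rate Exclusion floor (default 0.8).
#' @return List: `kept` calls table, `excluded` sample ids,
#'   `sample_rates`.
#' @export
exclude_low_call_samples <- function(calls, min_rate = 0.8) {
  rates <- calls[, list(rate = mean(!is.na(call))), by = "sample"]
  excluded <- rates$sample[rates$rate < min_rate]
  list(kept = calls[!calls$sample %in% excluded, ],
       excluded = excluded, sample_rates = rates)
}

#' Chi-squared segregation test for DH (1:1) or F2 (1:2:1) designs
#'
#' Pearson goodness-of-fit without continuity correction, df = classes - 1.
#' A heterozygote class observed in a DH design is flagged inconsistent and
#' dropped before testing the two homozygote classes.
#'
#' @param counts Genotype class counts ordered by ascending theta center
#'   (DH: 2 homozygote classes, possibly 3 with a spurious middle class;
#'   F2: AA, AB, BB).
#' @param design `"DH"` or `"F2"`.
#' @return List: `statistic`, `df`, `p`, `distorted` (p <= 0.05),
#'   `inconsistent` (DH with het class).
#' @export
segregation_test <- function(counts, design = c("DH", "F2")) {
  design <- match.arg(design)
  inconsistent <- FALSE
  if (design == "DH") {
    if (length(counts) == 3L) {
      inconsistent <- counts[2L] > 0L
      counts <- counts[c(1L, 3L)]
    }
    stopifnot(length(counts) == 2L)
    expected_p <- c(0.5, 0.5)
  } else {
    stopifnot(length(counts) == 3L)
    expected_p <- c(0.25, 0.5, 0.25)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, p = expected_p))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, distorted = ht$p.value <= 0.05,
       inconsistent = inconsistent)
}

#' Flag an assay as hemi-SNP or simple from its pooled cluster count
#'
#' A simple SNP yields at most three theta groups (AA, AB, BB) however the
#' populations are combined; an assay whose probes co-amplify a second,
#' population-differentiated locus splits into four or more groups once
#' the populations are pooled.
#'
#' @param pooled_model `cluster_model` fitted on the pooled populations.
#' @return `"hemi"` or `"simple"`.
#' @export
hemi_snp_flag <- function(pooled_model) {
  if (pooled_model$k >= 4L) "hemi" else "simple"
}

#' Reproducibility of replicate genotype calls
#'
#' @param calls Vector of replicate calls for one assay (NA = no-call).
#'   No-calls are ignored as long as at least two concordant calls remain.
#' @return TRUE/FALSE, or NA when fewer than two calls are available.
#' @export
reproducibility_check <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) < 2L) return(NA)
  length(unique(calls)) == 1L
}

#' Designability-score filter and class labels
#'
#' Assays scoring at or below the cutoff are excluded from the pool;
#' scores below 0.4 predict a low conversion success rate, 0.4 to 0.6
#' moderate, above 0.6 high.
#'
#' @param scores Numeric rank scores in \[0, 1\].
#' @param cutoff Exclusion threshold (default 0.85; `score <= cutoff`
#'   is excluded).
#' @return data.table: `rank_score`, `kept`, `class`.
#' @export
designability_filter <- function(scores, cutoff = 0.85) {
  stopifnot(all(scores >= 0 & scores <= 1))
  cls <- ifelse(scores < 0.4, "low",
                ifelse(scores <= 0.6, "moderate", "high"))
  data.table::data.table(rank_score = scores, kept = scores > cutoff,
                         class = cls)
}

#' Full per-assay GoldenGate analysis
#'
#' For every assay: theta transform, per-population and pooled cluster
#' fits, genotype calls with the no-call rules, assay and sample call
#' rates (samples below the 0.8 across-assay call rate are excluded and
#' rates recomputed once), parent-based polymorphism, segregation tests
#' (DH 1:1 when two clusters, F2 1:2:1 when three), replicate
#' reproducibility, and the pooled-cluster hemi flag.
#'
#' @param gg A `goldengate_data` simulation (or any object with the same
#'   `intensities` / `samples` layout).
#' @param k_max Maximum clusters per fit.
#' @param min_normR,max_dist No-call rules for [call_gg_genotypes()].
#' @param min_sample_rate Sample exclusion floor.
#' @return List of class `goldengate_result`: `assays` (per-assay table),
#'   `calls` (long call table), `excluded_samples`, `sample_rates`.
#' @export
analyze_goldengate <- function(gg, k_max = 6L, min_normR = 1500,
                               max_dist = 0.1, min_sample_rate = 0.8) {
  ints <- data.table::copy(gg$intensities)
  tt <- theta_transform(ints$Cy3, ints$Cy5)
  ints$theta <- tt$theta
  ints$normR <- tt$normR

  fit_and_call <- function(sub) {
    usable <- !is.na(sub$theta) & sub$normR >= min_normR
    if (sum(usable) < 2L)
      return(list(model = NULL, call = rep(NA_integer_, nrow(sub))))
    model <- fit_clusters(sub$theta[usable], k_max = k_max)
    cal <- call_gg_genotypes(model, sub$theta, sub$normR,
                             min_normR = min_normR, max_dist = max_dist)
    list(model = model, call = cal$call)
  }

  call_rows <- list()
  assay_rows <- list()
  for (as_id in unique(ints$assay)) {
    sub <- ints[ints$assay == as_id, ]
    dh <- sub[sub$population == "DH", ]
    f2 <- sub[sub$population == "F2", ]
    fit_dh <- fit_and_call(dh)
    fit_f2 <- fit_and_call(f2)
    fit_all <- fit_and_call(sub)

    calls <- rbind(
      data.table::data.table(sample = dh$sample, population = "DH",
                             role = dh$role, assay = as_id,
                             call = fit_dh$call),
      data.table::data.table(sample = f2$sample, population = "F2",
                             role = f2$role, assay = as_id,
                             call = fit_f2$call))
    call_rows[[as_id]] <- calls

    k_dh <- if (is.null(fit_dh$model)) NA_integer_ else fit_dh$model$k
    k_f2 <- if (is.null(fit_f2$model)) NA_integer_ else fit_f2$model$k
    k_pooled <- if (is.null(fit_all$model)) NA_integer_ else fit_all$model$k

    parent_call <- function(calls, pop, who)
      calls$call[calls$population == pop & calls$sample == who]
    poly_dh <- isTRUE(parent_call(calls, "DH", "DH_P1") !=
                      parent_call(calls, "DH", "DH_P2"))
    poly_f2 <- isTRUE(parent_call(calls, "F2", "F2_P1") !=
                      parent_call(calls, "F2", "F2_P2"))

    seg_dh <- seg_f2 <- list(statistic = NA_real_, p = NA_real_,
                             distorted = NA)
    if (poly_dh && !is.na(k_dh) && k_dh %in% c(2L, 3L)) {
      cnt <- tabulate(calls$call[calls$population == "DH" &
                                   calls$role == "line"], nbins = k_dh)
      seg_dh <- segregation_test(cnt, "DH")
    }
    if (poly_f2 && !is.na(k_f2) && k_f2 == 3L) {
      cnt <- tabulate(calls$call[calls$population == "F2" &
                                   calls$role == "line"], nbins = 3L)
      seg_f2 <- segregation_test(cnt, "F2")
    }

    rep_calls <- calls$call[calls$role %in% c("line", "replicate") &
                              calls$sample %in% c(
                                gg$samples$sample[gg$samples$role == "replicate"],
                                unique(gg$samples$replicate_of[
                                  !is.na(gg$samples$replicate_of)]))]
    assay_rows[[as_id]] <- data.table::data.table(
      assay = as_id,
      call_rate = mean(!is.na(calls$call)),
      k_dh = k_dh, k_f2 = k_f2, k_pooled = k_pooled,
      polymorphic = poly_dh || poly_f2,
      poly_dh = poly_dh, poly_f2 = poly_f2,
      seg_p_dh = seg_dh$p, seg_p_f2 = seg_f2$p,
      hemi_flag = if (is.na(k_pooled)) NA_character_
                  else hemi_snp_flag(fit_all$model),
      reproducible = reproducibility_check(rep_calls))
  }

  calls <- data.table::rbindlist(call_rows)
  ex <- exclude_low_call_samples(calls, min_rate = min_sample_rate)
  assays <- data.table::rbindlist(assay_rows)
  if (length(ex$excluded)) {
    rates2 <- ex$kept[, list(call_rate = mean(!is.na(call))), by = "assay"]
    assays$call_rate <- rates2$call_rate[match(assays$assay, rates2$assay)]
  }
  if (!is.null(gg$assays) && "rank_score" %in% names(gg$assays))
    assays$rank_score <- gg$assays$rank_score[match(assays$assay,
                                                    gg$assays$assay)]
  structure(list(assays = assays, calls = calls,
                 excluded_samples = ex$excluded,
                 sample_rates = ex$sample_rates),
            class = "goldengate_result")
}

#' @export
print.goldengate_result <- function(x, ...) {
  cat("GoldenGate analysis:", nrow(x$assays), "assays; mean call rate",
      sprintf("%.1f%%;", 100 * mean(x$assays$call_rate, na.rm = TRUE)),
      sum(x$assays$hemi_flag == "hemi", na.rm = TRUE), "hemi-flagged\n")
  invisible(x)
}
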