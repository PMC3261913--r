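# Deterministic 1-D Gaussian mixture EM with a shared component variance
# (all clusters of one assay share the same noise, and a common variance
# avoids the degenerate solutions of free-variance 1-D mixtures): centers
# initialized on the quantile grid (no random starts), shared sd floored
# at .SD_FLOOR so noise-free clusters stay finite, tolerance 1e-8 on the
# log-likelihood, <= 500 iterations.
.SD_FLOOR <- 1e-3

.em_1d <- function(x, k, max_iter = 500L, tol = 1e-8, init = NULL) {
  n <- length(x)
  mu <- init %||%
    as.numeric(quantile(x, (seq_len(k) - 0.5) / k, names = FALSE))
  s0 <- if (n > 1L) sd(x) else 0
  s <- max(s0 / k, .SD_FLOOR, na.rm = TRUE)
  w <- rep(1 / k, k)
  ll_old <- -Inf; ll <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s),
                   numeric(n))
    if (k == 1L) dens <- matrix(dens, ncol = 1L)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(resp * x) / nk
    s <- max(sqrt(sum(resp * (outer(x, mu, "-"))^2) / n), .SD_FLOOR)
    w <- nk / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(centers = mu[ord], sds = rep(s, k)[ord], weights = w[ord],
       loglik = ll, k = k)
}

#' Fit a cluster model to one marker's allelic-ratio data
#'
#' Fits 1-D Gaussian mixtures with 1..`k_max` components to the theta
#' values of a single marker and selects the component count by BIC.
#' Initialization is a fixed quantile grid, so the fit is deterministic
#' given the data.  Diploid SNPs produce up to three clusters at
#' \{0, 1/2, 1\}; MSVs produce mixed-ratio clusters on the quarter grid,
#' with five clusters when both paralogs segregate.
#'
#' @param theta numeric vector of allelic-ratio values in \[0, 1\]
#'   (NAs dropped).
#' @param marker_id optional id carried through to the result.
#' @param k_max maximum number of clusters considered.
#' @param min_sep minimum fitted center separation for a model to be
#'   eligible (dosage clusters are at least 1/4 apart).
#' @return an object of class `tm_clustermodel`: `k`, ascending `centers`,
#'   `sds`, `weights`, `fit_score` (BIC of the chosen model) and `n`.
#'   Fewer than 10 usable values gives `k = 0` with flag `low_n`.
#' @export
fit_clusters <- function(theta, marker_id = NA_character_, k_max = 5L,
                         min_sep = 0.1) {
  x <- theta[!is.na(theta)]
  n <- length(x)
  if (n < 10L)
    return(structure(list(marker_id = marker_id, k = 0L, centers = numeric(),
                          sds = numeric(), weights = numeric(),
                          fit_score = NA_real_, n = n, flag = "low_n"),
                     class = "tm_clustermodel"))
  best <- NULL; best_bic <- Inf
  for (k in seq_len(k_max)) {
    fit <- .em_multistart(x, k)
    # clamping at 0/1 leaves point masses that a free mixture would chase
    # by splitting clusters; genuine dosage clusters sit >= 0.25 apart, so
    # fits with closer centers are overfits and are not eligible
    if (k > 1L && min(diff(fit$centers)) < min_sep) next
    bic <- -2 * fit$loglik + 2 * k * log(n)  # k centers, k-1 weights, 1 sd
    if (bic < best_bic - 1e-9) {
      best <- fit; best_bic <- bic
    }
  }
  structure(list(marker_id = marker_id, k = best$k, centers = best$centers,
                 sds = best$sds, weights = best$weights,
                 fit_score = best_bic, n = n, flag = NULL),
            class = "tm_clustermodel")
}

# Deterministic multi-start for one k: the quantile grid, an equal-spaced
# grid over the data range, and every contiguous window of the canonical
# quarter grid (0, 1/4, 1/2, 3/4, 1) and half grid (0, 1/2, 1) of length k.
# Quantile inits alone can miss a sparse extreme dosage cluster.
.em_multistart <- function(x, k) {
  inits <- list(NULL, seq(min(x), max(x), length.out = k))
  for (grid in list(c(0, .25, .5, .75, 1), c(0, .5, 1))) {
    if (length(grid) < k) next
    for (st in seq_len(length(grid) - k + 1L))
      inits[[length(inits) + 1L]] <- grid[st:(st + k - 1L)]
  }
  best <- NULL
  for (ini in inits) {
    fit <- .em_1d(x, k, init = ini)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  best
}

# do all |centers - targets| fall within tol?
.centers_match <- function(centers, targets, tol) {
  length(centers) == length(targets) && all(abs(centers - targets) <= tol)
}

#' Classify a marker from its cluster model
#'
#' Applies the cluster-pattern rules: five clusters indicate an MSV-5 (both
#' paralogs segregating), one cluster a monomorphic assay, two or three
#' clusters on the diploid grid \{0, 1/2, 1\} a regular SNP, and three
#' tightly-spaced clusters on a quarter-grid half (\{0, 1/4, 1/2\} or
#' \{1/2, 3/4, 1\}) an MSV-3 -- MSV clusters must be tight (`max sd <=
#' tight_sd`) since mixed allelic ratios pack clusters closer together than
#' diploid SNPs do.  Everything else fails QC with flag `pattern_mismatch`.
#'
#' @param model a [fit_clusters()] result.
#' @param center_tol tolerance for matching cluster centers to canonical
#'   grids.
#' @param tight_sd maximum cluster sd for the MSV-3 call.
#' @return list with `marker_id`, `klass` (`SNP`, `MSV3`, `MSV5`, `MONO` or
#'   `FAIL`), `qc_flags` (character vector) and `msv3_offset` (0 or 2: the
#'   dosage of the fixed paralog, `NA` unless `klass == "MSV3"`).
#' @export
classify_marker <- function(model, center_tol = 0.08, tight_sd = 0.03) {
  out <- list(marker_id = model$marker_id, klass = "FAIL",
              qc_flags = character(), msv3_offset = NA_integer_)
  if (!is.null(model$flag) && model$flag == "low_n") {
    out$qc_flags <- "low_n"
    return(out)
  }
  k <- model$k; ctr <- model$centers
  if (k == 5L) {
    out$klass <- "MSV5"
  } else if (k == 1L) {
    out$klass <- "MONO"
  } else if (k %in% c(2L, 3L)) {
    snp_targets <- if (k == 3L) list(c(0, 0.5, 1)) else
      list(c(0, 0.5), c(0, 1), c(0.5, 1))
    is_snp <- any(vapply(snp_targets, .centers_match, TRUE,
                         centers = ctr, tol = center_tol))
    if (is_snp) {
      out$klass <- "SNP"
    } else if (k == 3L && max(model$sds) <= tight_sd &&
               (.centers_match(ctr, c(0, 0.25, 0.5), center_tol) ||
                .centers_match(ctr, c(0.5, 0.75, 1), center_tol))) {
      out$klass <- "MSV3"
      out$msv3_offset <- if (ctr[1] > 0.25) 2L else 0L
    } else {
      out$qc_flags <- "pattern_mismatch"
    }
  } else {
    out$qc_flags <- "pattern_mismatch"
  }
  out
}

#' Call dosage genotypes from a fitted cluster model
#'
#' Assigns each sample the dosage of its maximum-posterior cluster.
#' Cluster centers map to dosages linearly: theta 0 is dosage 0 and theta 1
#' the class maximum (2 for SNPs, 4 for MSVs), so e.g. an MSV-3 on the
#' upper half-grid calls dosages 2..4 including the fixed paralog's
#' contribution.  Posteriors below `call_threshold` are set missing.
#'
#' @param model a [fit_clusters()] result.
#' @param classification a [classify_marker()] result (class must not be
#'   `FAIL` or `MONO`).
#' @param theta named numeric vector of theta values (names = sample ids).
#' @param call_threshold minimum posterior for a non-missing call.
#' @return data frame `marker_id`, `sample_id`, `dosage`, `posterior`.
#' @export
call_genotypes <- function(model, classification, theta,
                           call_threshold = 0.95) {
  if (classification$klass %in% c("FAIL", "MONO"))
    .tm_stop("marker %s has class %s: no genotypes to call",
             classification$marker_id, classification$klass)
  dmax <- if (classification$klass == "SNP") 2L else 4L
  dose_of_cluster <- as.integer(round(model$centers * dmax))
  x <- as.numeric(theta)
  xs <- x
  xs[is.na(xs)] <- -1  # placeholder; masked below
  dens <- vapply(seq_len(model$k), function(j)
    model$weights[j] * dnorm(xs, model$centers[j], model$sds[j]),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  tot[tot < 1e-300] <- 1e-300
  post <- dens / tot
  best <- max.col(post, ties.method = "first")
  pmaxv <- post[cbind(seq_along(x), best)]
  dosage <- dose_of_cluster[best]
  bad <- is.na(x) | pmaxv < call_threshold
  dosage[bad] <- NA_integer_
  pmaxv[is.na(x)] <- NA_real_
  data.frame(marker_id = classification$marker_id,
             sample_id = names(theta) %||% as.character(seq_along(x)),
             dosage = as.integer(dosage), posterior = pmaxv)
}

#' Cluster, classify and call every marker of an intensity table
#'
#' Convenience driver running [fit_clusters()], [classify_marker()] and
#' [call_genotypes()] over a long intensity table.
#'
#' @param intensities data frame `marker_id`, `sample_id`, `theta` (and
#'   optionally `R`).
#' @param k_max,center_tol,tight_sd,call_threshold passed through.
#' @return list with `calls` (long data frame), `classifications` (data
#'   frame `marker_id`, `klass`, `msv3_offset`, `qc_flags`) and `models`.
#' @export
call_markers <- function(intensities, k_max = 5L, center_tol = 0.08,
                         tight_sd = 0.03, call_threshold = 0.95) {
  split_idx <- split(seq_len(nrow(intensities)), intensities$marker_id)
  models <- list(); cls <- list(); calls <- list()
  for (m in names(split_idx)) {
    idx <- split_idx[[m]]
    th <- setNames(intensities$theta[idx], intensities$sample_id[idx])
    mod <- fit_clusters(th, marker_id = m, k_max = k_max)
    cl <- classify_marker(mod, center_tol = center_tol, tight_sd = tight_sd)
    models[[m]] <- mod
    cls[[m]] <- data.frame(marker_id = m, klass = cl$klass,
                           msv3_offset = cl$msv3_offset,
                           qc_flags = paste(cl$qc_flags, collapse = ";"))
    if (!cl$klass %in% c("FAIL", "MONO"))
      calls[[m]] <- call_genotypes(mod, cl, th,
                                   call_threshold = call_threshold)
  }
  list(calls = do.call(rbind, unname(calls)),
       classifications = do.call(rbind, unname(cls)),
       models = models)
}
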