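# Two-level permutation framework: surrogate z-scored pointwise maps,
# sign-flip and condition-label nulls, sum-of-z cluster statistics with
# exceedance-mass max-statistic correction, plus the regression-across-trials
# and repeated-measures ANOVA used for the within-block beta decline.
#
# Construction (identical for every test): the observed statistic is the
# mean map across units (sessions or trials); each surrogate re-averages
# after a random relabeling; every point's z is
# (observed - surrogate mean) / surrogate SD, and its p comes from the
# normal CDF of z (two-sided). Cluster correction thresholds the pointwise
# p at 0.05, forms sign-segregated contiguous clusters (4-connectivity in
# frequency x time), scores each by the sum of its z values (exceedance
# mass), and compares against the permutation distribution of per-surrogate
# maximum |cluster mass|.

# Coerce a list of equally shaped maps (vectors or matrices) to a matrix of
# units x points; remembers the original dim.
as_unit_matrix <- function(maps) {
  d <- dim(maps[[1]]) %||% length(maps[[1]])
  U <- do.call(rbind, lapply(maps, as.vector))
  list(U = U, dim = d)
}

statmap_from_surrogates <- function(obs, surr, map_dim, n_perm, empirical_p = FALSE) {
  mu <- colMeans(surr)
  sdv <- col_sds(surr)
  sdv[sdv == 0] <- NA_real_
  z <- (obs - mu) / sdv
  z[is.na(z)] <- 0
  p <- if (empirical_p) {
    pmin(1, (1 + colSums(sweep(abs(surr - matrix(mu, nrow(surr), ncol(surr), byrow = TRUE)), 2, abs(obs - mu), `>=`))) / (n_perm + 1))
  } else 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
  zs <- sweep(sweep(surr, 2, mu), 2, ifelse(is.na(sdv), 1, sdv), `/`)
  structure(list(observed = obs, surr_mean = mu, surr_sd = sdv, z = z, p = p,
                 surr_z = zs, dim = map_dim, n_perm = n_perm),
            class = "fp_statmap")
}

#' @export
print.fp_statmap <- function(x, ...) {
  cat(sprintf("<fp_statmap> %s points, %d permutations; %d points with p < 0.05\n",
              paste(x$dim, collapse = " x "), x$n_perm, sum(x$p < 0.05)))
  invisible(x)
}

#' Sign-flip permutation test of a mean map against zero
#'
#' Each unit (session or trial) contributes one difference map; surrogates
#' multiply every unit's map by an independent fair +/-1 and re-average
#' (equivalently: subtract baseline from task or task from baseline at
#' random).
#'
#' @param maps List of equally shaped numeric maps (vectors, time series, or
#'   frequency x time matrices), one per unit.
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer seed.
#' @param empirical_p Use empirical rank p-values instead of the default
#'   normal-CDF-of-z construction.
#' @return An `fp_statmap` (holds the per-permutation z maps needed by
#'   [cluster_correct()]).
#' @export
signflip_test <- function(maps, n_perm = 200, seed = NULL, empirical_p = FALSE) {
  if (length(maps) < 2) stop("need >= 2 units")
  if (n_perm < 20) warning("n_perm < 20: surrogate moments will be unstable")
  um <- as_unit_matrix(maps)
  nu <- nrow(um$U)
  S <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * nu, replace = TRUE), n_perm, nu))
  surr <- S %*% um$U / nu
  statmap_from_surrogates(colMeans(um$U), surr, um$dim, n_perm, empirical_p)
}

#' Condition-label permutation test (paired or pooled)
#'
#' Paired design (session level): unit i contributes maps `a_i` and `b_i`;
#' surrogates swap the two labels independently per unit, which is a sign
#' flip of the per-unit difference. Pooled design (trial level): all maps are
#' exchangeable and surrogates shuffle the labels of the pooled set
#' (unbalanced groups allowed).
#'
#' @param maps_a,maps_b Lists of equally shaped maps. Paired: same length,
#'   unit-matched (units with a missing member are dropped with a warning).
#'   Pooled: arbitrary lengths.
#' @param paired Logical (default TRUE).
#' @inheritParams signflip_test
#' @return An `fp_statmap` for the contrast `mean(a) - mean(b)`.
#' @export
label_permutation_test <- function(maps_a, maps_b, n_perm = 200, seed = NULL,
                                   paired = TRUE, empirical_p = FALSE) {
  if (paired) {
    n <- min(length(maps_a), length(maps_b))
    miss <- vapply(seq_len(n), function(i)
      is.null(maps_a[[i]]) || is.null(maps_b[[i]]), logical(1))
    if (length(maps_a) != length(maps_b) || any(miss))
      warning("paired design with missing members: unmatched units dropped")
    keep <- which(!miss)
    diffs <- lapply(keep, function(i) maps_a[[i]] - maps_b[[i]])
    return(signflip_test(diffs, n_perm = n_perm, seed = seed,
                         empirical_p = empirical_p))
  }
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 1 || nb < 1) stop("both groups need >= 1 unit")
  um <- as_unit_matrix(c(maps_a, maps_b))
  nu <- na + nb
  # each permutation is encoded as a contrast row: +1/na for units labeled
  # "a", -1/nb for "b"
  P <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      lab <- rep(-1 / nb, nu)
      lab[sample.int(nu, na)] <- 1 / na
      lab
    }, numeric(nu)))
  })
  obs <- colMeans(um$U[seq_len(na), , drop = FALSE]) -
    colMeans(um$U[na + seq_len(nb), , drop = FALSE])
  surr <- P %*% um$U
  statmap_from_surrogates(obs, surr, um$dim, n_perm, empirical_p)
}

# Label contiguous TRUE regions; 1D uses run-length encoding, 2D uses
# 4-connectivity on the (frequency, time) grid via graph components.
label_components <- function(mask) {
  if (is.null(dim(mask)) || length(dim(mask)) == 1) {
    lab <- integer(length(mask))
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- 0
    for (j in seq_along(r$values)) if (r$values[j]) {
      k <- k + 1
      lab[starts[j]:ends[j]] <- k
    }
    return(lab)
  }
  nr <- nrow(mask)
  cells <- which(mask)
  lab <- integer(length(mask))
  dim(lab) <- dim(mask)
  if (!length(cells)) return(lab)
  row <- (cells - 1) %% nr + 1
  col <- (cells - 1) %/% nr + 1
  right <- cells[col < ncol(mask) & mask[pmin(cells + nr, length(mask))]]
  down <- cells[row < nr & mask[pmin(cells + 1, length(mask))]]
  e1 <- match(c(right, down), cells)
  e2 <- match(c(right + nr, down + 1), cells)
  g <- igraph::make_graph(as.vector(rbind(e1, e2)), n = length(cells),
                          directed = FALSE)
  lab[cells] <- igraph::components(g)$membership
  lab
}

# Clusters (per sign) of a z map: list of (cells, stat)
z_clusters <- function(z, zthr) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) z > zthr else z < -zthr
    lab <- label_components(mask)
    if (!any(lab > 0)) next
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k)
      out[[length(out) + 1]] <- list(cells = cells, sign = sgn,
                                     stat = sum(z[cells]))
    }
  }
  out
}

#' Exceedance-mass cluster correction of a permutation stat map
#'
#' Contiguous points with pointwise p below `threshold` form clusters
#' (positive and negative z separately; 4-connectivity for frequency x time
#' maps, runs for 1D maps). Each cluster's statistic is the sum of its z
#' values. The null distribution is the per-permutation maximum absolute
#' cluster statistic (per-sign maxima pooled by absolute value), and a
#' cluster's corrected p is the +1-smoothed fraction of surrogate maxima at
#' or above its absolute statistic.
#'
#' @param sm An `fp_statmap`.
#' @param threshold Pointwise two-sided alpha used to form clusters.
#' @param alpha Corrected significance level.
#' @return An object of class `fp_clusters`: `clusters` data.frame (`id`,
#'   `sign`, `n_points`, `stat`, `p_corrected`, `significant`), `mask`
#'   (integer cluster labels, observed map shape), `sig_mask` (logical),
#'   `max_stats` (surrogate maxima), `threshold`, `n_perm`.
#' @export
cluster_correct <- function(sm, threshold = 0.05, alpha = 0.05) {
  stopifnot(inherits(sm, "fp_statmap"))
  zthr <- stats::qnorm(1 - threshold / 2)
  zo <- sm$z
  dim(zo) <- if (length(sm$dim) > 1) sm$dim else NULL
  obs <- z_clusters(zo, zthr)
  max_stats <- vapply(seq_len(sm$n_perm), function(b) {
    zb <- sm$surr_z[b, ]
    dim(zb) <- if (length(sm$dim) > 1) sm$dim else NULL
    cl <- z_clusters(zb, zthr)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "stat")))
  }, numeric(1))
  mask <- integer(length(sm$z))
  dim(mask) <- if (length(sm$dim) > 1) sm$dim else NULL
  if (length(obs)) {
    stats_abs <- abs(vapply(obs, `[[`, numeric(1), "stat"))
    ord <- order(stats_abs, decreasing = TRUE)
    obs <- obs[ord]
    p_corr <- vapply(obs, function(cl)
      (1 + sum(max_stats >= abs(cl$stat))) / (sm$n_perm + 1), numeric(1))
    for (k in seq_along(obs)) mask[obs[[k]]$cells] <- k
    df <- data.frame(id = seq_along(obs),
                     sign = vapply(obs, `[[`, numeric(1), "sign"),
                     n_points = vapply(obs, function(cl) length(cl$cells), integer(1)),
                     stat = vapply(obs, `[[`, numeric(1), "stat"),
                     p_corrected = p_corr)
    df$significant <- df$p_corrected < alpha
  } else {
    df <- data.frame(id = integer(0), sign = numeric(0), n_points = integer(0),
                     stat = numeric(0), p_corrected = numeric(0),
                     significant = logical(0))
  }
  sig_mask <- array(FALSE, dim = dim(mask) %||% length(mask))
  if (any(df$significant))
    sig_mask[mask %in% df$id[df$significant]] <- TRUE
  structure(list(clusters = df, mask = mask, sig_mask = sig_mask,
                 max_stats = max_stats, threshold = threshold, alpha = alpha,
                 n_perm = sm$n_perm),
            class = "fp_clusters")
}

#' @export
print.fp_clusters <- function(x, ...) {
  cat(sprintf("<fp_clusters> %d clusters (%d significant at alpha=%g, %d permutations)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$alpha, x$n_perm))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Band-limited 1D cluster test
#'
#' Averages across the frequency band first, then runs the same permutation
#' machinery with 1D (time) contiguity: either each unit's band series
#' against zero (`"vs-baseline"`), or a paired a-vs-b contrast.
#'
#' @param series Either a list of per-unit numeric time series
#'   (`"vs-baseline"`) or, for `"a-vs-b"`, a list with elements `a` and `b`
#'   (lists of per-unit series).
#' @param contrast `"vs-baseline"` or `"a-vs-b"`.
#' @param n_perm,seed,threshold,alpha As in the parent tests.
#' @return `list(statmap, clusters)`.
#' @export
band_cluster_test <- function(series, contrast = c("vs-baseline", "a-vs-b"),
                              n_perm = 200, seed = NULL, threshold = 0.05,
                              alpha = 0.05) {
  contrast <- match.arg(contrast)
  sm <- if (contrast == "vs-baseline") {
    signflip_test(series, n_perm = n_perm, seed = seed)
  } else {
    label_permutation_test(series$a, series$b, n_perm = n_perm, seed = seed,
                           paired = TRUE)
  }
  list(statmap = sm, clusters = cluster_correct(sm, threshold, alpha))
}

#' Per-contact trial-level significance tests
#'
#' For each electrode contact, runs the trial-level sign-flip test of
#' normalized power against baseline and the trial-level condition-label
#' permutation (target vs distractor), each with cluster correction. The
#' unit of observation is the individual trial.
#'
#' @param contact_maps Named list; each element is a list of per-trial maps
#'   (matrices or series) of normalized power for one contact.
#' @param labels Factor/character of per-trial conditions (`"target"` /
#'   `"distractor"`), recycled across contacts, or a list parallel to
#'   `contact_maps`.
#' @param n_perm,seed,threshold,alpha Permutation parameters.
#' @param min_trials Contacts with fewer non-rejected trials are marked
#'   untestable.
#' @return `data.frame` with one row per contact: `contact`, `n_trials`,
#'   `testable`, `sig_baseline`, `sig_condition`, and the minimum corrected
#'   p of each test.
#' @export
per_electrode_tests <- function(contact_maps, labels, n_perm = 200,
                                seed = NULL, threshold = 0.05, alpha = 0.05,
                                min_trials = 10) {
  labs_list <- if (is.list(labels) && !is.data.frame(labels)) labels else
    rep(list(labels), length(contact_maps))
  res <- lapply(seq_along(contact_maps), function(i) {
    maps <- contact_maps[[i]]
    lab <- as.character(labs_list[[i]])
    n <- length(maps)
    if (n < min_trials)
      return(data.frame(contact = names(contact_maps)[i] %||% as.character(i),
                        n_trials = n, testable = FALSE, sig_baseline = NA,
                        sig_condition = NA, p_baseline = NA_real_,
                        p_condition = NA_real_))
    s1 <- derive_seed(seed %||% 1, "contact", i, 1)
    s2 <- derive_seed(seed %||% 1, "contact", i, 2)
    cb <- cluster_correct(signflip_test(maps, n_perm = n_perm, seed = s1),
                          threshold, alpha)
    cc <- cluster_correct(
      label_permutation_test(maps[lab == "target"], maps[lab == "distractor"],
                             n_perm = n_perm, seed = s2, paired = FALSE),
      threshold, alpha)
    pb <- if (nrow(cb$clusters)) min(cb$clusters$p_corrected) else 1
    pc <- if (nrow(cc$clusters)) min(cc$clusters$p_corrected) else 1
    data.frame(contact = names(contact_maps)[i] %||% as.character(i),
               n_trials = n, testable = TRUE,
               sig_baseline = any(cb$clusters$significant),
               sig_condition = any(cc$clusters$significant),
               p_baseline = pb, p_condition = pc)
  })
  do.call(rbind, res)
}

#' Regression of band power against trial number
#'
#' Per session, the correlation across trials between mean band power in the
#' 0-1000 ms task window and trial-in-block position (1..8); across sessions,
#' a one-sample t-test of the correlation coefficients against zero.
#'
#' @param power_by_session List of per-session numeric vectors (one band
#'   power value per trial).
#' @param position_by_session List of per-session trial-in-block positions.
#' @return `list(rho` (per session), `t`, `df`, `p`, `excluded)`.
#' @export
regress_band_vs_trialnum <- function(power_by_session, position_by_session) {
  stopifnot(length(power_by_session) == length(position_by_session),
            length(power_by_session) >= 2)
  rho <- rep(NA_real_, length(power_by_session))
  for (i in seq_along(power_by_session)) {
    x <- position_by_session[[i]]
    y <- power_by_session[[i]]
    if (length(unique(x)) < 3) stop("need >= 3 trial positions")
    if (stats::sd(y) == 0) next # constant series: rho undefined, excluded
    rho[i] <- stats::cor(x, y)
  }
  excluded <- which(is.na(rho))
  if (length(excluded))
    warning(sprintf("%d session(s) with constant power excluded", length(excluded)))
  r <- rho[!is.na(rho)]
  se <- stats::sd(r) / sqrt(length(r))
  if (is.na(se) || se == 0) {
    # all sessions identical (e.g. exact noiseless decline): t degenerates
    tval <- if (mean(r) == 0) 0 else sign(mean(r)) * Inf
    return(list(rho = rho, t = tval, df = length(r) - 1,
                p = if (mean(r) == 0) 1 else 0, excluded = excluded))
  }
  tt <- stats::t.test(r, mu = 0)
  list(rho = rho, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, excluded = excluded)
}

#' Repeated-measures ANOVA of band power across trial positions
#'
#' One-way (session x position matrix) or two-way with condition (session x
#' position x condition array, including the interaction term).
#'
#' @param x Matrix sessions x positions, or 3D array sessions x positions x
#'   conditions (dimnames of the 3rd axis label the conditions).
#' @return `data.frame(term, F, df1, df2, p)`; degenerate inputs (zero
#'   residual variance) yield `NA` F with a warning.
#' @export
rm_anova_trialnum <- function(x) {
  if (anyNA(x)) stop("incomplete design: missing cells")
  if (stats::var(as.vector(x)) == 0) {
    warning("degenerate input: zero variance (F undefined)")
    terms <- if (length(dim(x)) == 2) "pos" else c("pos", "cond", "pos:cond")
    return(data.frame(term = terms, F = NA_real_, df1 = NA_real_,
                      df2 = NA_real_, p = NA_real_))
  }
  if (length(dim(x)) == 2) {
    if (ncol(x) < 2 || nrow(x) < 2) stop("need >= 2 sessions and >= 2 positions")
    df <- data.frame(y = as.vector(x),
                     sess = factor(rep(seq_len(nrow(x)), ncol(x))),
                     pos = factor(rep(seq_len(ncol(x)), each = nrow(x))))
    fit <- stats::aov(y ~ pos + Error(sess / pos), data = df)
    tab <- summary(fit)[["Error: sess:pos"]][[1]]
    out <- data.frame(term = "pos", F = tab["pos", "F value"],
                      df1 = tab["pos", "Df"], df2 = tab["Residuals", "Df"],
                      p = tab["pos", "Pr(>F)"])
  } else {
    d <- dim(x)
    if (any(d[2:3] < 2)) stop("fewer than 2 levels of a factor")
    conds <- dimnames(x)[[3]] %||% paste0("c", seq_len(d[3]))
    df <- data.frame(y = as.vector(x),
                     sess = factor(rep(seq_len(d[1]), d[2] * d[3])),
                     pos = factor(rep(rep(seq_len(d[2]), each = d[1]), d[3])),
                     cond = factor(rep(conds, each = d[1] * d[2])))
    fit <- stats::aov(y ~ pos * cond + Error(sess / (pos * cond)), data = df)
    s <- summary(fit)
    grab <- function(stratum, term) {
      tab <- s[[stratum]][[1]]
      data.frame(term = term, F = tab[term, "F value"], df1 = tab[term, "Df"],
                 df2 = tab["Residuals", "Df"], p = tab[term, "Pr(>F)"])
    }
    out <- rbind(grab("Error: sess:pos", "pos"),
                 grab("Error: sess:cond", "cond"),
                 grab("Error: sess:pos:cond", "pos:cond"))
  }
  rownames(out) <- NULL
  if (anyNA(out$F)) warning("degenerate input: zero residual variance")
  out
}

# Exact sign-flip enumeration (oracle for small unit counts; exported so the
# acceptance report can compare the sampled test against it).

#' Exhaustive sign-flip test over all 2^n sign patterns
#'
#' Exact counterpart of [signflip_test()] for small unit counts: the
#' surrogate ensemble enumerates every sign assignment once.
#'
#' @param maps List of per-unit maps (at most ~16 units).
#' @return An `fp_statmap` whose surrogate ensemble is the full enumeration.
#' @export
signflip_enumerate <- function(maps) {
  um <- as_unit_matrix(maps)
  nu <- nrow(um$U)
  if (nu > 16) stop("enumeration limited to <= 16 units")
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), nu)))
  surr <- S %*% um$U / nu
  statmap_from_surrogates(colMeans(um$U), surr, um$dim, nrow(S))
}
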