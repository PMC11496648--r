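## Convergent cross mapping over fragmented composites.

## Evaluate a function with a temporary RNG state so that seeded
## operations are reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic fan-out of a master seed into per-task seeds (< 2^31).
derive_seed <- function(master, i) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

## Internal state shared by one recipient's cross-mapping: the recipient's
## delay embedding, pairwise distances, and the donor target vector
## (optionally lag-shifted, masked at fragment boundaries).
cross_map_state <- function(recipient, donor, E, lag = 0L) {
  stopifnot(inherits(recipient, "composite_series"),
            inherits(donor, "composite_series"))
  if (length(donor$values) != length(recipient$values)) {
    stop("recipient and donor composites must share fragment structure")
  }
  block <- build_lagged_block(recipient, E, target = "none")
  n <- length(donor$values)
  src <- block$t + lag
  ok <- src >= 1L & src <= n
  ok[ok] <- donor$fragment[src[ok]] == block$fragment[ok]
  y <- rep(NA_real_, length(src))
  y[ok] <- donor$values[src[ok]]
  rows <- which(ok)
  list(block = block, y = y, rows = rows,
       D = as.matrix(stats::dist(block$X[rows, , drop = FALSE])))
}

## Predict the target over all valid rows given a library subset (indices
## into `state$rows`); returns the Pearson rho of predictions vs observed.
cross_map_eval <- function(state, lib_idx, k) {
  y <- state$y[state$rows]
  n <- length(state$rows)
  pred <- rep(NA_real_, n)
  if (length(lib_idx) <= k) {
    ## small-library fast path: every library row is a neighbor, so the
    ## whole draw reduces to vectorized row operations
    M <- state$D[, lib_idx, drop = FALSE]
    in_lib <- match(seq_len(n), lib_idx)
    sel <- which(!is.na(in_lib))
    M[cbind(sel, in_lib[sel])] <- Inf      # predictee is never its own neighbor
    dmin <- do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
    w <- exp(-M / dmin)
    dup <- which(dmin == 0)
    if (length(dup) > 0L) {
      w[dup, ] <- (M[dup, , drop = FALSE] == 0) * 1
    }
    w[!is.finite(w)] <- 0
    sw <- rowSums(w)
    pred <- as.vector(w %*% y[lib_idx]) / sw
    pred[sw == 0] <- NA_real_
  } else {
    for (p in seq_len(n)) {
      cand <- lib_idx[lib_idx != p]
      d <- state$D[p, cand]
      sw <- simplex_weights(d, k)
      pred[p] <- sum(sw$w * y[cand[sw$nb]]) / sum(sw$w)
    }
  }
  ok <- is.finite(pred)
  if (sum(ok) < 3L || stats::sd(pred[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(y[ok], pred[ok])
}

#' Cross map a donor from a recipient's reconstructed manifold
#'
#' The recipient (the putatively affected variable) is delay-embedded at
#' dimension E; for each of `n_samples` random library subsets of L rows
#' (drawn uniformly without replacement), every valid embedding row is
#' predicted as the simplex-weighted average of the donor's contemporaneous
#' values at its E+1 nearest library neighbors (the predictee itself is
#' never its own neighbor). Skill in recovering the donor from the
#' recipient's manifold is evidence that the donor causally forces the
#' recipient.
#'
#' @param recipient,donor `composite_series` sharing fragment structure.
#' @param E Embedding dimension for the recipient manifold.
#' @param L Library length (number of embedded rows made available),
#'   `E+1 <= L <=` available rows.
#' @param n_samples Number of random library draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param lag Donor time offset: the target is the donor value at `t + lag`
#'   (rows whose shifted target leaves the fragment are masked).
#' @return Numeric vector of Pearson rho, one per draw. When `L` equals the
#'   number of available rows every draw is the full library, so the
#'   (identical) deterministic value is replicated.
#' @export
cross_map <- function(recipient, donor, E, L, n_samples = 100L, seed = NULL,
                      lag = 0L) {
  state <- cross_map_state(recipient, donor, E, lag = lag)
  n_avail <- length(state$rows)
  k <- E + 1L
  if (L < k) stop(sprintf("library length L=%d below minimum E+1=%d", L, k))
  if (L > n_avail) {
    stop(sprintf("library length L=%d exceeds available rows (%d)", L, n_avail))
  }
  if (n_avail == 0L) stop("no valid rows for cross mapping")
  if (L == n_avail) {
    rho <- cross_map_eval(state, seq_len(n_avail), k)
    return(rep(rho, n_samples))
  }
  with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      lib <- sample.int(n_avail, L)
      cross_map_eval(state, lib, k)
    }, numeric(1))
  })
}

#' Library lengths used for the CCM convergence test
#'
#' Minimum `E + 1`; maximum all embeddable rows (for the complete
#' 24-fragment, 10-census design this is `24 * (10 - (E - 1))`).
#'
#' @param recipient A `composite_series`.
#' @param E Embedding dimension.
#' @return List with `Lmin`, `Lmax`.
#' @export
ccm_library_range <- function(recipient, E) {
  f <- recipient$fragments
  list(Lmin = E + 1L, Lmax = sum(pmax(0L, f$len - (E - 1L))))
}

#' CCM convergence (criterion 1)
#'
#' Compares mean cross-map skill at the minimum and maximum library
#' lengths; convergence requires the gain `delta_rho = rho(Lmax) -
#' rho(Lmin)` to exceed `delta_min` (default 0.1).
#'
#' @inheritParams cross_map
#' @param n_samples Random library draws per length (default 1000).
#' @param delta_min Convergence threshold on the skill gain.
#' @return List: `Lmin`, `Lmax`, `rho_min`, `rho_max` (means over draws),
#'   `rho_min_sd`, `delta_rho`, `pass`.
#' @export
ccm_convergence <- function(recipient, donor, E, n_samples = 1000L,
                            seed = NULL, delta_min = 0.1) {
  lr <- ccm_library_range(recipient, E)
  rho_lo <- cross_map(recipient, donor, E, L = lr$Lmin,
                      n_samples = n_samples, seed = seed)
  rho_hi <- cross_map(recipient, donor, E, L = lr$Lmax, n_samples = 1L,
                      seed = derive_seed(seed, 2L))
  rho_min <- mean(rho_lo, na.rm = TRUE)
  rho_max <- mean(rho_hi, na.rm = TRUE)
  delta <- rho_max - rho_min
  list(Lmin = lr$Lmin, Lmax = lr$Lmax, rho_min = rho_min, rho_max = rho_max,
       rho_min_sd = stats::sd(rho_lo, na.rm = TRUE),
       delta_rho = delta, pass = is.finite(delta) && delta > delta_min)
}

#' Seasonal surrogate series for a composite
#'
#' Treats the composite as one consecutive series with a fixed
#' `cycle`-census seasonal period. The mean seasonal profile (mean value at
#' each census position, over all fragments holding that position) is kept
#' fixed; anomalies from the profile are randomly permuted among the
#' composite positions sharing a census position, so every surrogate
#' preserves the cyclic mean profile exactly while its anomaly multiset is
#' a permutation of the original anomalies.
#'
#' @param series A `composite_series`.
#' @param cycle Cycle length in censuses (default 10; fragments shorter
#'   than the cycle contribute only the positions they observed).
#' @param n Number of surrogates.
#' @param seed Optional integer seed.
#' @return A `surrogate_set`: matrix `surrogates` (length x n), the
#'   seasonal `profile`, `positions`, `seed`, `cycle`.
#' @export
seasonal_surrogate <- function(series, cycle = 10L, n = 1000L, seed = NULL) {
  stopifnot(inherits(series, "composite_series"))
  pos <- ((series$census - 1L) %% cycle) + 1L
  prof <- tapply(series$values, pos, mean)
  prof_at <- as.numeric(prof[as.character(pos)])
  anom <- series$values - prof_at
  idx_by_pos <- split(seq_along(pos), pos)
  sur <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = length(pos), ncol = n)
    for (j in seq_len(n)) {
      s <- prof_at
      for (ii in idx_by_pos) {
        s[ii] <- s[ii] + anom[if (length(ii) > 1L) sample(ii) else ii]
      }
      out[, j] <- s
    }
    out
  })
  structure(list(taxon = series$taxon, surrogates = sur, profile = prof,
                 positions = pos, anomalies = anom, seed = seed,
                 cycle = cycle),
            class = "surrogate_set")
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n)`; never exactly zero.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null draws.
#' @return One-sided p-value.
#' @export
permutation_pvalue <- function(observed, null) {
  null <- null[is.finite(null)]
  (1 + sum(null >= observed)) / (1 + length(null))
}

## Fixed neighbor weights of the recipient manifold at full library:
## prediction of any target vector is then a single sparse linear map,
## which makes the 1000-surrogate null distribution a matrix product.
full_library_weights <- function(state, k) {
  n <- length(state$rows)
  W <- matrix(0, n, n)
  for (p in seq_len(n)) {
    cand <- seq_len(n)[-p]
    sw <- simplex_weights(state$D[p, cand], k)
    nb <- cand[sw$nb]
    W[p, nb] <- sw$w / sum(sw$w)
  }
  W
}

#' Seasonal-surrogate significance of cross-map skill (criterion 2)
#'
#' The null distribution replaces the donor (target) series by each
#' surrogate while keeping the recipient manifold intact: the same
#' full-library neighbor weights predict each surrogate, and the observed
#' skill at the maximum library length is ranked against the null skills
#' with the add-one permutation formula.
#'
#' @inheritParams cross_map
#' @param surrogates A `surrogate_set` built from the donor series.
#' @return List: `rho_obs`, `p` (one-sided), `null_rho` vector.
#' @export
surrogate_test <- function(recipient, donor, E, surrogates) {
  stopifnot(inherits(surrogates, "surrogate_set"))
  state <- cross_map_state(recipient, donor, E)
  k <- E + 1L
  W <- full_library_weights(state, k)
  tv <- state$block$t[state$rows]
  y_obs <- state$y[state$rows]
  rho_obs <- safe_cor(y_obs, W %*% y_obs)
  Y <- surrogates$surrogates[tv, , drop = FALSE]
  P <- W %*% Y
  null_rho <- colwise_cor(Y, P)
  list(rho_obs = rho_obs, p = permutation_pvalue(rho_obs, null_rho),
       null_rho = null_rho)
}

safe_cor <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

colwise_cor <- function(A, B) {
  n <- nrow(A)
  ca <- sweep(A, 2, colMeans(A))
  cb <- sweep(B, 2, colMeans(B))
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Lagged CCM screening (criterion 3)
#'
#' Cross-maps the donor at time offsets `lags` (default -2..+2) from the
#' recipient manifold at maximum library length and locates the offset with
#' the best mean skill. Best skill at a positive offset (the manifold
#' "predicting" the donor's future better than its present or past) is a
#' false-positive signal, so acceptance requires the optimal lag <= 0. Ties
#' are broken towards the smallest absolute lag, then the more negative
#' lag.
#'
#' @inheritParams cross_map
#' @param lags Integer offsets to scan.
#' @param n_samples Random library draws per lag (draws at full library are
#'   degenerate and evaluated once).
#' @return List: `rho_by_lag` (named by lag; `NA` when every row is
#'   masked), `optimal_lag`, `pass`.
#' @export
lagged_ccm <- function(recipient, donor, E, lags = -2:2, n_samples = 100L,
                       seed = NULL) {
  rho <- vapply(seq_along(lags), function(i) {
    lag <- lags[i]
    st <- tryCatch(cross_map_state(recipient, donor, E, lag = lag),
                   error = function(e) NULL)
    if (is.null(st) || length(st$rows) < E + 2L) return(NA_real_)
    L <- length(st$rows)
    mean(cross_map(recipient, donor, E, L = L, n_samples = n_samples,
                   seed = derive_seed(seed, i), lag = lag), na.rm = TRUE)
  }, numeric(1))
  names(rho) <- as.character(lags)
  if (all(is.na(rho))) {
    return(list(rho_by_lag = rho, optimal_lag = NA_integer_, pass = FALSE))
  }
  best <- max(rho, na.rm = TRUE)
  cand <- lags[!is.na(rho) & rho == best]
  cand <- cand[order(abs(cand), cand)]   # smallest |lag|, then more negative
  opt <- cand[1L]
  list(rho_by_lag = rho, optimal_lag = as.integer(opt), pass = opt <= 0L)
}

#' Detect causal links among all taxa by the three-criterion CCM cascade
#'
#' Every ordered donor-recipient pair is tested sequentially: (1)
#' convergence `delta_rho > delta_min`; (2) seasonal-surrogate significance
#' of the skill at maximum library length (`p < alpha` accepts, `alpha <= p
#' < marginal_alpha` marks the link marginal); (3) lagged-CCM screening
#' (optimal lag <= 0). A later criterion is evaluated only if every earlier
#' one passed, so pairs failing convergence never consume surrogate
#' computation (their `p_surrogate` is `NA`). Donor surrogate sets are
#' generated lazily and cached across pairs.
#'
#' @param composites Named list of `composite_series` (all taxa).
#' @param E Named integer vector of embedding dimensions per taxon (see
#'   [select_embeddings()]).
#' @param n_samples CCM library draws (default 1000).
#' @param n_surrogates Seasonal surrogates per donor (default 1000).
#' @param lag_samples Draws per lag in lagged CCM (default 100).
#' @param delta_min Convergence threshold (default 0.1).
#' @param alpha,marginal_alpha Significance and marginal thresholds
#'   (defaults 0.05 and 0.1).
#' @param cycle Seasonal cycle length for surrogates (default 10).
#' @param seed Master seed; per-pair seeds are derived deterministically.
#' @return A `ccm_scan`: `table` (one row per ordered pair with rho at both
#'   library lengths, `delta_rho`, `p_surrogate`, `opt_lag`, `decision`,
#'   `criterion_failed`) and `links` (accepted + marginal pairs).
#' @export
detect_links <- function(composites, E, n_samples = 1000L,
                         n_surrogates = 1000L, lag_samples = 100L,
                         delta_min = 0.1, alpha = 0.05, marginal_alpha = 0.1,
                         cycle = 10L, seed = NULL) {
  taxa <- names(composites)
  stopifnot(!is.null(taxa), all(taxa %in% names(E)))
  pairs <- expand.grid(donor = taxa, recipient = taxa,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$donor != pairs$recipient, , drop = FALSE]
  rownames(pairs) <- NULL
  surr_cache <- new.env(parent = emptyenv())
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    dn <- pairs$donor[i]; rc <- pairs$recipient[i]
    Ei <- E[[rc]]
    cv <- ccm_convergence(composites[[rc]], composites[[dn]], Ei,
                          n_samples = n_samples,
                          seed = derive_seed(seed, i))
    rec <- data.frame(donor = dn, recipient = rc, E = Ei,
                      Lmin = cv$Lmin, Lmax = cv$Lmax, rho_min = cv$rho_min,
                      rho_max = cv$rho_max, delta_rho = cv$delta_rho,
                      p_surrogate = NA_real_, opt_lag = NA_integer_,
                      decision = "reject", criterion_failed = NA_character_,
                      stringsAsFactors = FALSE)
    if (!cv$pass) {
      rec$criterion_failed <- "convergence"
      res[[i]] <- rec
      next
    }
    if (!exists(dn, envir = surr_cache)) {
      assign(dn, seasonal_surrogate(composites[[dn]], cycle = cycle,
                                    n = n_surrogates,
                                    seed = derive_seed(seed, 10000L + match(dn, taxa))),
             envir = surr_cache)
    }
    st <- surrogate_test(composites[[rc]], composites[[dn]], Ei,
                         get(dn, envir = surr_cache))
    rec$p_surrogate <- st$p
    if (!is.finite(st$p) || st$p >= marginal_alpha) {
      rec$criterion_failed <- "surrogate"
      res[[i]] <- rec
      next
    }
    lc <- lagged_ccm(composites[[rc]], composites[[dn]], Ei,
                     n_samples = lag_samples,
                     seed = derive_seed(seed, 20000L + i))
    rec$opt_lag <- lc$optimal_lag
    if (!lc$pass) {
      rec$criterion_failed <- "lagged_ccm"
      res[[i]] <- rec
      next
    }
    rec$decision <- if (st$p < alpha) "accept" else "marginal"
    res[[i]] <- rec
  }
  tab <- do.call(rbind, res)
  links <- tab[tab$decision %in% c("accept", "marginal"),
               c("donor", "recipient", "decision")]
  rownames(links) <- NULL
  structure(list(table = tab, links = links), class = "ccm_scan")
}

#' @export
print.ccm_scan <- function(x, ...) {
  cat(sprintf("<ccm_scan: %d pairs tested, %d accepted, %d marginal>\n",
              nrow(x$table), sum(x$table$decision == "accept"),
              sum(x$table$decision == "marginal")))
  invisible(x)
}

#' Write a CCM scan to CSV / JSON
#'
#' @param scan A `ccm_scan`.
#' @param csv_path Output CSV for the full pair table.
#' @param json_path Optional JSON edge list of accepted/marginal links.
#' @return Invisibly `csv_path`.
#' @export
write_ccm_scan <- function(scan, csv_path, json_path = NULL) {
  utils::write.csv(scan$table, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(scan$links, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
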