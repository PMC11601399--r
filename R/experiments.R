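#' Experiment configuration
#'
#' Bundles the task condition (set size, stripe count, chunking), training
#' schedule and dopamine gains. Defaults follow the study conditions: 500
#' training epochs of 100 trials, with seed counts scaled to desk use.
#'
#' @param set_size Items stored per episode before the recall probe.
#' @param n_stripes Allocated PFC stripes.
#' @param chunk_enabled Is stripe 1 chunk-linked?
#' @param n_epochs Training epochs (default 500).
#' @param trials_per_epoch Trials per epoch (default 100); episodes of
#'   \code{set_size + 1} trials are packed to fill it.
#' @param n_orientations Discrete orientation inventory K (>= set_size).
#' @param seeds Integer vector of random seeds (distinct).
#' @param burst_gain,dip_gain Dopamine burst/dip gains.
#' @param n_eval_episodes Post-training evaluation episodes (learning off).
#' @param network Named list of extra \code{\link{networkConfig}} overrides.
#' @return A list of class \code{experiment_config}.
#' @export
experimentConfig <- function(set_size = 2, n_stripes = 2,
                             chunk_enabled = TRUE, n_epochs = 500,
                             trials_per_epoch = 100, n_orientations = 8,
                             seeds = 1:10, burst_gain = 0.6,
                             dip_gain = 0.6, n_eval_episodes = 250,
                             network = list()) {
  stopifnot(n_epochs >= 1, trials_per_epoch >= 1, set_size >= 1,
            n_eval_episodes >= 1)
  if (set_size > n_orientations)
    stop("set_size (", set_size, ") exceeds n_orientations (",
         n_orientations, ")")
  if (anyDuplicated(seeds))
    stop("seeds must be distinct")
  if (trials_per_epoch < set_size + 1)
    stop("trials_per_epoch smaller than one episode (set_size + 1)")
  structure(list(set_size = as.integer(set_size),
                 n_stripes = as.integer(n_stripes),
                 chunk_enabled = isTRUE(chunk_enabled),
                 n_epochs = as.integer(n_epochs),
                 trials_per_epoch = as.integer(trials_per_epoch),
                 n_orientations = as.integer(n_orientations),
                 seeds = as.integer(seeds),
                 burst_gain = burst_gain, dip_gain = dip_gain,
                 n_eval_episodes = as.integer(n_eval_episodes),
                 network = network),
            class = "experiment_config")
}

buildNetworkConfig <- function(config) {
  args <- utils::modifyList(
    list(n_stripes = config$n_stripes,
         chunk_enabled = config$chunk_enabled,
         n_orientations = config$n_orientations,
         burst_gain = config$burst_gain,
         dip_gain = config$dip_gain),
    config$network)
  do.call(networkConfig, args)
}

## pack a list of episode specs into the engine's matrix form
packEpisodes <- function(episodes) {
  maxN <- max(vapply(episodes, function(e) e$set_size, 1L))
  n <- length(episodes)
  oris <- matrix(0L, n, maxN)
  cols <- matrix(0, n, maxN)
  Ns <- integer(n)
  probe <- integer(n)
  for (i in seq_len(n)) {
    e <- episodes[[i]]
    Ns[i] <- e$set_size
    oris[i, seq_len(e$set_size)] <- e$orientations
    cols[i, seq_len(e$set_size)] <- e$colors
    probe[i] <- e$probe_index
  }
  list(oris = oris, colors = cols, N = Ns, probe = probe)
}

#' Train one network
#'
#' Runs the full training schedule through the compiled engine, logging
#' per-epoch recall performance and the evolving input-gating policy.
#' Fully reproducible from the seed.
#'
#' @param config An \code{\link{experimentConfig}}.
#' @param seed Integer seed for this run.
#' @return A list of class \code{pbwm_trained}: the trained \code{network},
#'   \code{config}, \code{seed}, a per-epoch \code{log} data frame
#'   (mean_abs_error, nonresponse_rate, mean_output_gated, mean_reward) and
#'   \code{alpha}, the epochs-by-stripes gating-policy trace.
#' @export
trainNetwork <- function(config, seed) {
  set.seed(seed)
  net <- createNetwork(buildNetworkConfig(config))
  epi_per_epoch <- config$trials_per_epoch %/% (config$set_size + 1L)
  n_ep <- config$n_epochs
  log <- data.frame(epoch = seq_len(n_ep), mean_abs_error = NA_real_,
                    nonresponse_rate = NA_real_,
                    mean_output_gated = NA_real_, mean_reward = NA_real_)
  alpha <- matrix(NA_real_, n_ep, config$n_stripes)
  for (ep in seq_len(n_ep)) {
    eps <- replicate(epi_per_epoch,
                     makeEpisode(config$set_size, config$n_orientations),
                     simplify = FALSE)
    pk <- packEpisodes(eps)
    out <- cpp_run_episodes(net, pk$oris, pk$colors, pk$N, pk$probe, TRUE)
    net <- out$net
    rc <- out$recall
    log$mean_abs_error[ep] <- mean(abs(rc$error_deg))
    log$nonresponse_rate[ep] <- mean(rc$responded == 0)
    log$mean_output_gated[ep] <- mean(rc$n_output_gated)
    log$mean_reward[ep] <- mean(rc$reward)
    alpha[ep, ] <- gatingPolicyAlpha(net$Wgo_in, net$Wnogo_in)
    if (any(!is.finite(rc$error_deg)))
      stop("training diverged at epoch ", ep)
  }
  structure(list(network = net, config = config, seed = seed,
                 log = log, alpha = alpha),
            class = "pbwm_trained")
}

#' @export
print.pbwm_trained <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf(
    "<pbwm_trained> seed %d, %d epochs; final mean |error| %.1f deg, nonresponse %.1f%%\n",
    x$seed, n, x$log$mean_abs_error[n], 100 * x$log$nonresponse_rate[n]))
  invisible(x)
}

#' Evaluate a trained network with learning frozen
#'
#' Runs fresh episodes through the trained network with plasticity off
#' (gating exploration noise stays on: the learned policy, not a greedy
#' readout, is what the behavioral analyses characterize).
#'
#' @param trained A \code{pbwm_trained} (or bare \code{pbwm_network}).
#' @param n_episodes Number of evaluation episodes.
#' @param set_size,n_orientations Task condition; default from the training
#'   config when available.
#' @return A list: \code{recall} (one row per recall trial, including
#'   \code{error_deg}, \code{responded}, \code{n_output_gated}, \code{lag}),
#'   \code{occupancy} (episodes-by-stripes occupancy after the final store
#'   trial), \code{items} (episodes-by-set-size color matrix, radians) and
#'   \code{probe_index}.
#' @export
evalNetwork <- function(trained, n_episodes = 250, set_size = NULL,
                        n_orientations = NULL) {
  net <- if (inherits(trained, "pbwm_trained")) trained$network else trained
  cfg <- if (inherits(trained, "pbwm_trained")) trained$config else NULL
  if (is.null(set_size)) set_size <- cfg$set_size
  if (is.null(n_orientations))
    n_orientations <- if (is.null(cfg)) net$config$n_orientations
                      else cfg$n_orientations
  eps <- replicate(n_episodes, makeEpisode(set_size, n_orientations),
                   simplify = FALSE)
  pk <- packEpisodes(eps)
  out <- cpp_run_episodes(net, pk$oris, pk$colors, pk$N, pk$probe, FALSE)
  list(recall = out$recall, occupancy = out$occupancy_final_store,
       items = pk$colors, probe_index = pk$probe)
}

#' Train and evaluate over a set of seeds
#'
#' @param config An \code{\link{experimentConfig}}.
#' @param progress Print a line per seed?
#' @return List with \code{runs} (per-seed list of \code{trained} and
#'   \code{eval}) and \code{recall}, the pooled evaluation recall table
#'   with a \code{seed} column.
#' @export
runExperiment <- function(config, progress = FALSE) {
  runs <- lapply(config$seeds, function(s) {
    tr <- trainNetwork(config, s)
    ev <- evalNetwork(tr, config$n_eval_episodes)
    if (progress)
      message(sprintf("seed %d: mean |error| %.1f deg", s,
                      mean(abs(ev$recall$error_deg))))
    list(trained = tr, eval = ev)
  })
  recall <- do.call(rbind, lapply(seq_along(runs), function(i) {
    df <- runs[[i]]$eval$recall
    df$seed <- config$seeds[i]
    df
  }))
  list(runs = runs, recall = recall)
}

#' Gating-policy strength per stripe
#'
#' Rectified normalized Go-minus-NoGo summed synaptic strength from the
#' orientation control inputs to the input-gating pools:
#' \code{alpha = max(0, (sum(Go) - sum(NoGo)) / (sum(Go) + sum(NoGo)))},
#' defined as 0 when all weights are zero. Invariant to uniform rescaling
#' of the weights.
#'
#' @param go_w,nogo_w K-by-n orientation weight matrices.
#' @return Numeric vector of alpha in [0, 1] per stripe.
#' @export
gatingPolicyAlpha <- function(go_w, nogo_w) {
  sg <- colSums(go_w)
  sn <- colSums(nogo_w)
  tot <- sg + sn
  ifelse(tot > 0, pmax(0, (sg - sn) / tot), 0)
}

#' Gating-policy trace across training
#'
#' @param trained A \code{pbwm_trained}.
#' @return Data frame with epoch, stripe, stripe type and alpha.
#' @export
gatingPolicyTrace <- function(trained) {
  a <- trained$alpha
  ns <- ncol(a)
  chunk <- trained$network$config$chunk_stripe
  data.frame(
    epoch = rep(seq_len(nrow(a)), ns),
    stripe = rep(seq_len(ns), each = nrow(a)),
    type = rep(ifelse(seq_len(ns) == chunk, "chunk", "input"),
               each = nrow(a)),
    alpha = as.numeric(a))
}

#' Analytic chance-recall probability
#'
#' Probability that uniformly random, independent gating (each item placed
#' into one of n stripes with overwriting, then one stripe read out
#' uniformly) both preserves the first stored item and reads it out:
#' \code{(n - 1)^(N - 1) / n^N}, which reduces to 1/n at N = 1.
#'
#' @param n_stripes Number of stripes n (>= 1).
#' @param set_size Set size N (>= 1).
#' @return Probability in [0, 1].
#' @export
chanceRecallProbability <- function(n_stripes, set_size) {
  stopifnot(n_stripes >= 1, set_size >= 1)
  (n_stripes - 1)^(set_size - 1) / n_stripes^set_size
}

#' Von Mises + uniform mixture fit of recall errors
#'
#' Errors on the circle are modelled as a mixture of a uniform "guess"
#' component and a zero-centered circular-normal (von Mises) "memory"
#' component; the fitted uniform weight is the guess rate.
#'
#' @param errors_deg Signed errors in degrees in [-180, 180).
#' @param bin_width_deg Histogram bin width (degrees).
#' @return List with \code{histogram} (data frame: mid, count, density),
#'   \code{guess_rate}, \code{kappa}, \code{sd_deg} (circular SD of the
#'   memory component) and \code{n}; flags \code{low_confidence} when fewer
#'   than 100 trials are supplied.
#' @export
errorHistogramAndGuessRate <- function(errors_deg, bin_width_deg = 10) {
  stopifnot(all(errors_deg >= -180), all(errors_deg < 180))
  breaks <- seq(-180, 180, by = bin_width_deg)
  h <- graphics::hist(errors_deg, breaks = breaks, plot = FALSE)
  x <- errors_deg * pi / 180
  nll <- function(par) {
    g <- stats::plogis(par[1])
    k <- exp(par[2])
    dens <- g / (2 * pi) +
      (1 - g) * exp(k * (cos(x) - 1)) / (2 * pi * besselI(k, 0, TRUE))
    -sum(log(pmax(dens, 1e-300)))
  }
  ## kappa is bounded below: an unconcentrated memory component is
  ## indistinguishable from the uniform component (flat ridge at kappa=0)
  fit <- stats::optim(c(0, log(5)), nll, method = "L-BFGS-B",
                      lower = c(-12, log(2)), upper = c(12, 8))
  g <- stats::plogis(fit$par[1])
  k <- exp(fit$par[2])
  sd_deg <- sqrt(-2 * log(besselI(k, 1, TRUE) / besselI(k, 0, TRUE))) *
    180 / pi
  list(histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density),
       guess_rate = g, kappa = k, sd_deg = sd_deg,
       n = length(errors_deg),
       low_confidence = length(errors_deg) < 100)
}

#' Stripe usage on maximum-load store trials
#'
#' @param occupancy Episodes-by-stripes logical/0-1 matrix of occupancy
#'   after the final store trial of each episode.
#' @return List with \code{per_stripe} usage fractions,
#'   \code{all_occupied} (fraction of episodes with every stripe occupied)
#'   and \code{any_empty} (fraction with at least one empty stripe).
#' @export
stripeUsage <- function(occupancy) {
  occupancy <- as.matrix(occupancy) * 1
  list(per_stripe = colMeans(occupancy),
       all_occupied = mean(rowSums(occupancy) == ncol(occupancy)),
       any_empty = mean(rowSums(occupancy) < ncol(occupancy)))
}

#' Out-of-cluster variance (circular SD, degrees)
#'
#' Circular standard deviation of the non-probed items' color angles;
#' wraparound-safe (items at 350 and 10 degrees are 20 degrees apart).
#'
#' @param other_deg Angles of the non-probed items, in degrees (>= 2).
#' @return Dispersion in degrees; 0 for identical items.
#' @export
ocv <- function(other_deg) {
  if (length(other_deg) < 2)
    stop("OCV needs at least 2 non-probed items")
  a <- other_deg * pi / 180
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sqrt(-2 * log(min(rbar, 1))) * 180 / pi
}

#' Mean absolute recall error binned by OCV
#'
#' @param ocv_deg Per-trial OCV values (degrees).
#' @param abs_error_deg Per-trial absolute recall errors (degrees).
#' @param breaks OCV bin edges (degrees).
#' @return Data frame with bin label, midpoint, n and mean absolute error
#'   (NA for empty bins, which are reported, not dropped).
#' @export
ocvBinnedError <- function(ocv_deg, abs_error_deg,
                           breaks = seq(0, 105, by = 15)) {
  stopifnot(length(ocv_deg) == length(abs_error_deg))
  bin <- cut(ocv_deg, breaks, include.lowest = TRUE, right = FALSE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(bin = levels(bin), mid = mids, n = 0L,
                    mean_abs_error = NA_real_)
  agg <- tapply(abs_error_deg, bin, mean)
  cnt <- tapply(abs_error_deg, bin, length)
  idx <- match(names(agg), out$bin)
  out$mean_abs_error[idx] <- as.numeric(agg)
  out$n[idx] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Attach OCV values to evaluation results
#'
#' @param eval_result Result of \code{\link{evalNetwork}} at set size >= 3.
#' @return The recall table with an \code{ocv} column (degrees).
#' @export
evalWithOcv <- function(eval_result) {
  rc <- eval_result$recall
  items <- eval_result$items
  pr <- eval_result$probe_index
  rc$ocv <- vapply(seq_len(nrow(rc)), function(i) {
    others <- items[i, -pr[i]] * 180 / pi
    ocv(others)
  }, numeric(1))
  rc
}

#' Mean absolute recall error by lag
#'
#' @param recall Recall table carrying \code{error_deg} and \code{lag}
#'   (intervening store trials between the probed item and recall).
#' @return Data frame with lag, n and mean absolute error; lags with no
#'   data are omitted.
#' @export
recencyCurve <- function(recall) {
  agg <- tapply(abs(recall$error_deg), recall$lag, mean)
  cnt <- tapply(recall$error_deg, recall$lag, length)
  data.frame(lag = as.integer(names(agg)),
             n = as.integer(cnt),
             mean_abs_error = as.numeric(agg))
}

#' Average number of stripes opened by output gating per recall trial
#'
#' @param recall Recall table carrying \code{n_output_gated}.
#' @return Arithmetic mean.
#' @export
meanOutputGated <- function(recall) mean(recall$n_output_gated)

#' Dopamine gain sweep
#'
#' Trains fresh networks for every (burst, dip) gain pair and records the
#' mean absolute recall error at evaluation, averaged over the config's
#' seeds. Runs that diverge are recorded as NA, not dropped.
#'
#' @param config Base \code{\link{experimentConfig}}.
#' @param burst_grid,dip_grid Gain grids (non-empty).
#' @return Matrix of mean absolute errors, rows = burst grid, cols = dip
#'   grid (dimnames carry the gains).
#' @export
daGainSweep <- function(config, burst_grid = c(0.1, 0.6, 1.2),
                        dip_grid = c(0.1, 0.6, 1.2)) {
  stopifnot(length(burst_grid) >= 1, length(dip_grid) >= 1)
  out <- matrix(NA_real_, length(burst_grid), length(dip_grid),
                dimnames = list(burst = as.character(burst_grid),
                                dip = as.character(dip_grid)))
  for (i in seq_along(burst_grid)) {
    for (j in seq_along(dip_grid)) {
      cfg <- config
      cfg$burst_gain <- burst_grid[i]
      cfg$dip_gain <- dip_grid[j]
      val <- tryCatch({
        ex <- runExperiment(cfg)
        mean(abs(ex$recall$error_deg))
      }, error = function(e) NA_real_)
      out[i, j] <- val
    }
  }
  out
}
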