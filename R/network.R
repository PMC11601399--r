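#' Default network configuration
#'
#' All tunable constants of the circuit in one list. Stripe layout follows
#' the minimal chunking architecture: when \code{chunk_enabled}, exactly one
#' stripe receives its candidate from the chunking ring layer and the
#' remaining \code{n_stripes - 1} stripes receive the raw sensory bump.
#'
#' @param n_stripes Number of PFC stripes (memory slots).
#' @param chunk_enabled Whether stripe 1 is chunk-linked.
#' @param ring_size Neurons per color ring.
#' @param n_orientations Discrete orientation inventory size K.
#' @param tuning_width Sensory bump tuning width (radians).
#' @param kernel_width Chunk-layer connection kernel width (radians).
#' @param ge_gain Overall gain on chunk-layer excitatory input.
#' @param scale_input,scale_pfc Relative projection scales of bottom-up
#'   input vs. top-down PFC drive onto the chunk layer (input stronger).
#' @param chunk_gamma Activation gain of chunk-layer neurons (graded, lower
#'   than the saturating default so merged bumps decode smoothly).
#' @param n_cycles Settling cycles for the chunk layer.
#' @param ori_overlap Similarity of the distributed control-input
#'   patterns of neighboring orientations, in [0, 1). Orientations are
#'   represented as overlapping population patterns over the K control
#'   units (unit k responds \code{ori_overlap^(d^2)} for circular
#'   orientation distance d), so reinforcement credit spreads to similar
#'   orientations, as it does between overlapping population codes.
#' @param noise_sd SD of additive Gaussian exploration noise on the
#'   Go-minus-NoGo gating margin (no random draws are consumed when 0).
#' @param decode_floor Activity floor below which no decode is possible.
#' @param occupy_floor Deep-layer peak activity defining an occupied stripe.
#' @param occ_drive_in,occ_drive_out Whether the per-stripe occupancy
#'   signal drives the input / output gating pools. By default it informs
#'   input gating only (helping route new items away from occupied
#'   stripes); the output competition is purely orientation-addressed.
#' @param occ_nogo_init Initial occupancy-to-NoGo weight on the input
#'   gating channel of input-linked stripes: occupied stripes start with a
#'   bias against being overwritten (robust maintenance resists
#'   interruption), which reinforcement can strengthen or unlearn. The
#'   chunk-linked stripe is exempt: its candidate already merges its own
#'   maintained content, so re-gating it is intrinsically non-destructive.
#' @param w_init Upper bound of the uniform random initial striatal
#'   weights. Small random (not zero) initial weights break the symmetry
#'   between stripes so that reinforcement can carve stripe-specific
#'   gating policies.
#' @param lr_v Critic learning rate.
#' @param lr_w Striatal three-factor learning rate.
#' @param lr_rep Supervised report-mapping learning rate.
#' @param tag_decay Multiplicative per-trial eligibility-tag retention.
#' @param nogo_tag_scale Relative eligibility credit given to NoGo
#'   (stayed-closed) gating decisions, in [0, 1]. 1 treats withholding a
#'   gate as fully credited an action as opening it; 0 restricts learning
#'   to opened gates (making collapsed policies absorbing).
#' @param nogo_burst_credit Fraction of the NoGo-side credit applied on
#'   dopamine bursts (dips always apply in full, reviving withheld
#'   gates); crediting a non-action for a success is weaker evidence
#'   than blaming it for a failure.
#' @param w_max Striatal weight ceiling.
#' @param burst_gain,dip_gain Dopamine gains on positive / negative RPEs.
#' @param maintain_leak Per-trial leak on unmodified deep bumps (0 = ideal
#'   latch).
#' @param fffb A \code{\link{fffbParams}} object for the chunk layer.
#' @param neuron A \code{\link{neuronParams}} object (chunk-layer gamma is
#'   overridden by \code{chunk_gamma}).
#' @return A list of class \code{network_config}.
#' @export
networkConfig <- function(n_stripes = 2, chunk_enabled = TRUE,
                          ring_size = 20, n_orientations = 8,
                          tuning_width = 0.875, kernel_width = 0.28,
                          ge_gain = 6, scale_input = 1, scale_pfc = 0.8,
                          chunk_gamma = 15, n_cycles = 50,
                          ori_overlap = 0.35, noise_sd = 0.1, decode_floor = 0.1,
                          occupy_floor = 0.3, occ_drive_in = TRUE,
                          occ_drive_out = FALSE, occ_nogo_init = 0.3,
                          w_init = 0.05,
                          lr_v = 0.05, lr_w = 0.1, lr_rep = 0.05,
                          tag_decay = 0.7, nogo_tag_scale = 0.35,
                          nogo_burst_credit = 1, w_max = 1,
                          burst_gain = 0.6, dip_gain = 0.6,
                          maintain_leak = 0,
                          fffb = fffbParams(Gi = 3, fb_tau = 3),
                          neuron = neuronParams()) {
  stopifnot(n_stripes >= 1, ring_size >= 4, n_orientations >= 1,
            noise_sd >= 0, tag_decay >= 0, tag_decay <= 1,
            burst_gain >= 0, dip_gain >= 0, w_max > 0,
            maintain_leak >= 0, maintain_leak < 1, w_init >= 0,
            nogo_tag_scale >= 0, nogo_tag_scale <= 1,
            ori_overlap >= 0, ori_overlap < 1,
            nogo_burst_credit >= 0, nogo_burst_credit <= 1)
  structure(list(n_stripes = as.integer(n_stripes),
                 chunk_enabled = isTRUE(chunk_enabled),
                 chunk_stripe = if (isTRUE(chunk_enabled)) 1L else 0L,
                 ring_size = as.integer(ring_size),
                 n_orientations = as.integer(n_orientations),
                 tuning_width = tuning_width,
                 kernel_width = kernel_width,
                 ge_gain = ge_gain,
                 scale_input = scale_input, scale_pfc = scale_pfc,
                 chunk_gamma = chunk_gamma,
                 n_cycles = as.integer(n_cycles),
                 ori_overlap = ori_overlap,
                 noise_sd = noise_sd,
                 decode_floor = decode_floor,
                 occupy_floor = occupy_floor,
                 occ_drive_in = isTRUE(occ_drive_in),
                 occ_drive_out = isTRUE(occ_drive_out),
                 occ_nogo_init = occ_nogo_init, w_init = w_init,
                 lr_v = lr_v, lr_w = lr_w, lr_rep = lr_rep,
                 tag_decay = tag_decay, nogo_tag_scale = nogo_tag_scale,
                 nogo_burst_credit = nogo_burst_credit,
                 w_max = w_max,
                 burst_gain = burst_gain, dip_gain = dip_gain,
                 maintain_leak = maintain_leak,
                 fffb = fffb, neuron = neuron),
            class = "network_config")
}

#' Create a fresh network
#'
#' Striatal Go/NoGo weights start at small uniform random values in
#' [0, w_init] - the gating policy is learned from scratch, but random
#' initial weights break the symmetry between stripes. The two plastic
#' report mappings start at zero (an untrained network cannot report) and
#' deep PFC layers start empty. Consumes random draws: create networks
#' after seeding.
#'
#' @param config A \code{\link{networkConfig}} object.
#' @return A list of class \code{pbwm_network} holding configuration,
#'   weights, eligibility tags, deep-layer state and the critic.
#' @export
createNetwork <- function(config = networkConfig()) {
  K <- config$n_orientations
  n <- config$n_stripes
  R <- config$ring_size
  ang <- ringAngles(R)
  kern <- outer(ang, ang, function(a, b)
    exp(-circDiff(a, b)^2 / (2 * config$kernel_width^2)))
  zeroKn <- matrix(0, K, n)
  dk <- outer(seq_len(K), seq_len(K), function(a, b)
    pmin(abs(a - b), K - abs(a - b)))
  U <- if (config$ori_overlap > 0) config$ori_overlap^(dk^2) else (dk == 0) * 1
  rw <- function() matrix(stats::runif(K * n, 0, config$w_init), K, n)
  rv <- function() stats::runif(n, 0, config$w_init)
  structure(list(
    config = config,
    kernel = kern,
    U_ori = U,
    Wgo_in = rw(), Wnogo_in = rw(),
    Wgo_out = rw(), Wnogo_out = rw(),
    Wocc_go_in = rv(),
    Wocc_nogo_in = ifelse(seq_len(n) == config$chunk_stripe, 0,
                          config$occ_nogo_init) + rv(),
    Wocc_go_out = rv(), Wocc_nogo_out = rv(),
    Wrep_in = matrix(0, R, R), Wrep_pfc = matrix(0, R, R),
    tag_in = zeroKn, tag_nogo_in = zeroKn,
    tag_out = zeroKn, tag_nogo_out = zeroKn,
    tag_occ_in = numeric(n), tag_occ_nogo_in = numeric(n),
    tag_occ_out = numeric(n), tag_occ_nogo_out = numeric(n),
    deep = matrix(0, R, n),
    occupied = logical(n),
    v = 0),
    class = "pbwm_network")
}

#' @export
print.pbwm_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pbwm_network> %d stripes (%s), ring %d, K = %d orientations\n",
    cfg$n_stripes,
    if (cfg$chunk_enabled) "stripe 1 chunk-linked" else "no chunk layer",
    cfg$ring_size, cfg$n_orientations))
  cat(sprintf("  occupied stripes: %d / %d; critic v = %.3f\n",
              sum(x$occupied), cfg$n_stripes, x$v))
  invisible(x)
}

#' Chunk-layer settling step
#'
#' The posterior ring-attractor layer receives convergent excitation from
#' the sensory bump (stronger, relative scale \code{scale_input}) and from
#' the occupied PFC stripes' deep bumps (weaker, \code{scale_pfc},
#' normalized as one projection: the mean over occupied stripes, so
#' duplicated content cannot outweigh the sensory drive), through a
#' Gaussian topographic kernel; FFFB lateral inhibition then settles the
#' layer so that overlapping drives merge into a single attracted bump
#' while distant top-down bumps are suppressed.
#'
#' @param network A \code{pbwm_network}.
#' @param input_bump Sensory activity bump.
#' @return Settled chunk-layer activity vector.
#' @export
chunkLayerStep <- function(network, input_bump) {
  cfg <- network$config
  n <- cfg$ring_size
  groups <- list(list(x = input_bump, w = network$kernel,
                      scale = cfg$scale_input))
  occ <- which(network$occupied)
  for (s in occ)
    groups[[length(groups) + 1]] <- list(x = network$deep[, s],
                                         w = network$kernel,
                                         scale = cfg$scale_pfc / length(occ))
  ge <- cfg$ge_gain * excitatoryConductance(groups)
  neuron <- cfg$neuron
  neuron$gamma <- cfg$chunk_gamma
  settleRing(ge, n_cycles = cfg$n_cycles, neuron = neuron,
             fffb = cfg$fffb)$y
}

#' Basal-ganglia gating competition
#'
#' One independent Go/NoGo competition per stripe for one channel (input or
#' output gating). Pool activities are the learned weights from the active
#' control-input pattern (a one-hot or distributed orientation drive) plus,
#' for each stripe, an occupancy signal from its own deep layer. A gate
#' opens iff Go - NoGo + noise > 0.
#'
#' @param drive Length-K control-input activity vector (the probed or
#'   stored orientation's population pattern).
#' @param occupancy Numeric vector of per-stripe occupancy (0/1).
#' @param go_w,nogo_w K-by-n orientation weight matrices.
#' @param occ_go_w,occ_nogo_w Length-n occupancy weight vectors.
#' @param noise_sd Exploration noise SD (no draws consumed when 0).
#' @return List with \code{open} (logical), and a \code{record} data frame
#'   (stripe, go, nogo, noise, open).
#' @export
bgGateCompetition <- function(drive, occupancy, go_w, nogo_w,
                              occ_go_w, occ_nogo_w, noise_sd = 0) {
  go <- as.numeric(crossprod(go_w, drive)) + occupancy * occ_go_w
  nogo <- as.numeric(crossprod(nogo_w, drive)) + occupancy * occ_nogo_w
  noise <- if (noise_sd > 0) stats::rnorm(length(go), 0, noise_sd)
           else numeric(length(go))
  open <- (go - nogo + noise) > 0
  list(open = open,
       record = data.frame(stripe = seq_along(go), go = go, nogo = nogo,
                           noise = noise, open = open))
}

#' Apply input gating
#'
#' Each opened stripe replaces its maintained (deep) bump with its source
#' candidate - the raw sensory bump for input-linked stripes, the settled
#' chunk-layer bump for the chunk-linked stripe - peak-normalized. Closed
#' stripes keep their content exactly (idealized latch), up to the optional
#' maintenance leak.
#'
#' @param network A \code{pbwm_network}.
#' @param open Logical gate flags from \code{\link{bgGateCompetition}}.
#' @param input_bump Sensory bump.
#' @param chunk_bump Settled chunk bump (or NULL when no chunk layer).
#' @return The updated network.
#' @export
applyInputGating <- function(network, open, input_bump, chunk_bump = NULL) {
  cfg <- network$config
  leak <- cfg$maintain_leak
  for (s in seq_len(cfg$n_stripes)) {
    if (open[s]) {
      src <- if (s == cfg$chunk_stripe) chunk_bump else input_bump
      pk <- max(src)
      if (pk > cfg$occupy_floor) {
        network$deep[, s] <- src / pk
        network$occupied[s] <- TRUE
      } else {
        network$deep[, s] <- 0
        network$occupied[s] <- FALSE
      }
    } else if (leak > 0 && network$occupied[s]) {
      network$deep[, s] <- network$deep[, s] * (1 - leak)
      network$occupied[s] <- max(network$deep[, s]) > cfg$occupy_floor
      if (!network$occupied[s]) network$deep[, s] <- 0
    }
  }
  network
}

#' Apply output gating
#'
#' The response pathway is driven by the mean of the deep bumps of all
#' opened, occupied stripes (averaging, not summing, so reading out several
#' stripes "contaminates" rather than saturates the response). Opening no
#' occupied stripe is a non-response.
#'
#' @param network A \code{pbwm_network}.
#' @param open Logical output-gate flags.
#' @return List with \code{drive} (output-layer drive bump), \code{responded}
#'   and \code{n_output_gated} (count of opened gates).
#' @export
applyOutputGating <- function(network, open) {
  eff <- open & network$occupied
  responded <- any(eff)
  drive <- if (responded) rowMeans(network$deep[, eff, drop = FALSE])
           else numeric(network$config$ring_size)
  list(drive = drive, responded = responded,
       n_output_gated = sum(open))
}
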