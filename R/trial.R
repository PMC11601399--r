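#' Run one trial through the circuit (reference path)
#'
#' Readable R implementation of the full trial flow; the training loops use
#' the compiled engine, which follows exactly the same operation order and
#' random-number stream (per-stripe gating noise, then one uniform draw on
#' non-response recalls), so the two paths are interchangeable and are
#' cross-checked in the test suite.
#'
#' Store trial: encode the color, settle the chunk layer against current
#' PFC content, run the input-gating competition, tag opened gates, latch
#' gated stripes, and take one supervised delta-rule step on the
#' input-to-output report mapping. Recall trial: run the output-gating
#' competition, average the opened occupied stripes into the response
#' pathway, decode and score, and (when learning) dispatch the reward
#' through critic, dopamine and the three-factor striatal updates, then
#' clear the episode's eligibility tags.
#'
#' @param network A \code{pbwm_network}.
#' @param trial A list: \code{kind} ("store" or "recall") plus
#'   \code{orientation}, \code{color} (store) or
#'   \code{probe_orientation}, \code{target_angle}, \code{lag} (recall).
#' @param learn Apply plasticity?
#' @return List with the updated \code{network}, the trial \code{result}
#'   (a recall result for recall trials, a store report otherwise) and the
#'   gating \code{record}.
#' @export
runTrial <- function(network, trial, learn = TRUE) {
  cfg <- network$config
  if (trial$kind == "store") {
    x <- encodeColor(trial$color, cfg$ring_size, cfg$tuning_width)
    chunk_bump <- if (cfg$chunk_enabled) chunkLayerStep(network, x) else NULL
    occ_pre <- if (cfg$occ_drive_in) as.numeric(network$occupied)
               else numeric(cfg$n_stripes)
    u <- network$U_ori[trial$orientation + 1L, ]
    comp <- bgGateCompetition(u, occ_pre,
                              network$Wgo_in, network$Wnogo_in,
                              network$Wocc_go_in, network$Wocc_nogo_in,
                              cfg$noise_sd)
    if (learn) {
      ti <- updateTags(network$tag_in, network$tag_nogo_in,
                       network$tag_occ_in, network$tag_occ_nogo_in,
                       cfg$tag_decay, u, occ_pre,
                       comp$open, cfg$nogo_tag_scale)
      network$tag_in <- ti$tag_go
      network$tag_nogo_in <- ti$tag_nogo
      network$tag_occ_in <- ti$tag_occ_go
      network$tag_occ_nogo_in <- ti$tag_occ_nogo
      to <- updateTags(network$tag_out, network$tag_nogo_out,
                       network$tag_occ_out, network$tag_occ_nogo_out,
                       cfg$tag_decay)
      network$tag_out <- to$tag_go
      network$tag_nogo_out <- to$tag_nogo
      network$tag_occ_out <- to$tag_occ_go
      network$tag_occ_nogo_out <- to$tag_occ_nogo
    }
    network <- applyInputGating(network, comp$open, x, chunk_bump)
    produced <- as.numeric(network$Wrep_in %*% x)
    if (learn)
      network$Wrep_in <- reportMappingUpdate(network$Wrep_in, x, produced,
                                             x, cfg$lr_rep)
    report <- decodePopulation(pmax(produced, 0), floor = cfg$decode_floor)
    res <- list(kind = "store", orientation = trial$orientation,
                report_angle = report,
                gated_stripes = which(comp$open))
    return(list(network = network, result = res, record = comp$record))
  }

  ## recall trial
  occ_pre <- if (cfg$occ_drive_out) as.numeric(network$occupied)
             else numeric(cfg$n_stripes)
  u <- network$U_ori[trial$probe_orientation + 1L, ]
  comp <- bgGateCompetition(u, occ_pre,
                            network$Wgo_out, network$Wnogo_out,
                            network$Wocc_go_out, network$Wocc_nogo_out,
                            cfg$noise_sd)
  if (learn) {
    ti <- updateTags(network$tag_in, network$tag_nogo_in,
                     network$tag_occ_in, network$tag_occ_nogo_in,
                     cfg$tag_decay)
    network$tag_in <- ti$tag_go
    network$tag_nogo_in <- ti$tag_nogo
    network$tag_occ_in <- ti$tag_occ_go
    network$tag_occ_nogo_in <- ti$tag_occ_nogo
    to <- updateTags(network$tag_out, network$tag_nogo_out,
                     network$tag_occ_out, network$tag_occ_nogo_out,
                     cfg$tag_decay, u, occ_pre,
                     comp$open, cfg$nogo_tag_scale)
    network$tag_out <- to$tag_go
    network$tag_nogo_out <- to$tag_nogo
    network$tag_occ_out <- to$tag_occ_go
    network$tag_occ_nogo_out <- to$tag_occ_nogo
  }
  og <- applyOutputGating(network, comp$open)
  response <- NA_real_
  if (og$responded) {
    produced_raw <- as.numeric(network$Wrep_pfc %*% og$drive)
    response <- decodePopulation(pmax(produced_raw, 0),
                                 floor = cfg$decode_floor)
  }
  responded <- og$responded && !is.na(response)
  error_deg <- if (responded) signedCircularError(response, trial$target_angle)
               else stats::runif(1, -180, 180)
  reward <- rewardFromError(error_deg)
  delta <- NA_real_
  da <- NA_real_
  if (learn) {
    cr <- criticRpe(reward, network$v, cfg$lr_v)
    delta <- cr$delta
    network$v <- cr$v
    da <- dopamineSignal(delta, cfg$burst_gain, cfg$dip_gain)
    up <- striatalThreeFactorUpdate(network$Wgo_in, network$Wnogo_in,
                                    network$tag_in, da, cfg$lr_w, cfg$w_max,
                                    network$tag_nogo_in,
                                    cfg$nogo_burst_credit)
    network$Wgo_in <- up$go_w; network$Wnogo_in <- up$nogo_w
    up <- striatalThreeFactorUpdate(network$Wocc_go_in, network$Wocc_nogo_in,
                                    network$tag_occ_in, da, cfg$lr_w,
                                    cfg$w_max, network$tag_occ_nogo_in,
                                    cfg$nogo_burst_credit)
    network$Wocc_go_in <- up$go_w; network$Wocc_nogo_in <- up$nogo_w
    up <- striatalThreeFactorUpdate(network$Wgo_out, network$Wnogo_out,
                                    network$tag_out, da, cfg$lr_w, cfg$w_max,
                                    network$tag_nogo_out,
                                    cfg$nogo_burst_credit)
    network$Wgo_out <- up$go_w; network$Wnogo_out <- up$nogo_w
    up <- striatalThreeFactorUpdate(network$Wocc_go_out, network$Wocc_nogo_out,
                                    network$tag_occ_out, da, cfg$lr_w,
                                    cfg$w_max, network$tag_occ_nogo_out,
                                    cfg$nogo_burst_credit)
    network$Wocc_go_out <- up$go_w; network$Wocc_nogo_out <- up$nogo_w
    if (og$responded) {
      target <- encodeColor(trial$target_angle, cfg$ring_size,
                            cfg$tuning_width)
      network$Wrep_pfc <- reportMappingUpdate(network$Wrep_pfc, og$drive,
                                              as.numeric(network$Wrep_pfc %*%
                                                           og$drive),
                                              target, cfg$lr_rep)
    }
    ## episode boundary: recall ends the episode, tags do not leak across
    network$tag_in[] <- 0; network$tag_out[] <- 0
    network$tag_nogo_in[] <- 0; network$tag_nogo_out[] <- 0
    network$tag_occ_in[] <- 0; network$tag_occ_out[] <- 0
    network$tag_occ_nogo_in[] <- 0; network$tag_occ_nogo_out[] <- 0
  }
  res <- list(kind = "recall",
              response_deg = if (responded) signedCircularError(response, 0)
                             else NA_real_,
              target_deg = signedCircularError(trial$target_angle, 0),
              error_deg = error_deg, responded = responded,
              gated = og$responded, n_output_gated = og$n_output_gated,
              lag = trial$lag, reward = reward, delta = delta, da = da)
  list(network = network, result = res, record = comp$record)
}

#' Run a full episode (reference path)
#'
#' @param network A \code{pbwm_network}.
#' @param episode An \code{\link{makeEpisode}} spec.
#' @param learn Apply plasticity?
#' @return List with the updated \code{network}, the episode's recall
#'   \code{result} and \code{occupancy_final_store} (per-stripe occupancy
#'   right after the last store trial).
#' @export
runEpisode <- function(network, episode, learn = TRUE) {
  if (!episode$probe_orientation %in% episode$orientations)
    stop("malformed episode: recall probes an orientation never presented")
  for (i in seq_len(episode$set_size)) {
    tr <- list(kind = "store", orientation = episode$orientations[i],
               color = episode$colors[i])
    network <- runTrial(network, tr, learn)$network
  }
  occ <- network$occupied
  tr <- list(kind = "recall",
             probe_orientation = episode$probe_orientation,
             target_angle = episode$target_angle, lag = episode$lag)
  out <- runTrial(network, tr, learn)
  list(network = out$network, result = out$result,
       occupancy_final_store = occ)
}
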