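#' Rescorla-Wagner critic update
#'
#' The critic maintains a single scalar reward expectation v. The reward
#' prediction error is \code{delta = r - v}; v moves toward r by
#' \code{lr_v * delta}.
#'
#' @param reward Reward in [-1, 1].
#' @param v Current expectation.
#' @param lr_v Critic learning rate.
#' @return List with \code{delta} and updated \code{v}.
#' @export
criticRpe <- function(reward, v, lr_v = 0.05) {
  stopifnot(reward >= -1, reward <= 1)
  delta <- reward - v
  list(delta = delta, v = v + lr_v * delta)
}

#' Gain-scaled dopamine signal
#'
#' Positive RPEs are signalled as dopamine bursts scaled by
#' \code{burst_gain}; negative RPEs as dips scaled by \code{dip_gain}.
#' Sign-preserving, zero at zero RPE.
#'
#' @param delta Reward prediction error.
#' @param burst_gain,dip_gain Non-negative gains.
#' @return Scaled dopamine signal.
#' @export
dopamineSignal <- function(delta, burst_gain = 0.6, dip_gain = 0.6) {
  stopifnot(burst_gain >= 0, dip_gain >= 0)
  ifelse(delta > 0, burst_gain * delta, dip_gain * delta)
}

#' Eligibility-tag update for one gating channel
#'
#' All tags first decay multiplicatively; then each stripe that took part
#' in a gating competition this trial flags its decision: synapses from the
#' active drive inputs onto the Go pool of an opened gate, and onto the
#' NoGo pool of a gate that stayed closed, are incremented by pre-activity
#' (a one-hot orientation contributes pre = 1, the occupancy input its 0/1
#' occupancy at decision time). Tagging both outcomes lets dopamine credit
#' or blame the decision actually taken, so a policy that has collapsed to
#' "never gate" can still be revived by persistent negative RPEs.
#'
#' @param tag_go,tag_nogo K-by-n orientation tag matrices for the Go
#'   (opened) and NoGo (stayed-closed) pools.
#' @param tag_occ_go,tag_occ_nogo Length-n occupancy-input tag vectors.
#' @param decay Multiplicative retention in [0, 1].
#' @param drive Length-K control-input activity vector (or NULL: decay
#'   only); each tagged synapse is incremented by its pre-activity.
#' @param occupancy Per-stripe occupancy at decision time.
#' @param open Logical gate flags (or NULL: decay only).
#' @param nogo_scale Relative increment for NoGo-side (closed) decisions.
#' @return List with the four updated tag arrays.
#' @export
updateTags <- function(tag_go, tag_nogo, tag_occ_go, tag_occ_nogo, decay,
                       drive = NULL, occupancy = NULL,
                       open = NULL, nogo_scale = 1) {
  tag_go <- tag_go * decay
  tag_nogo <- tag_nogo * decay
  tag_occ_go <- tag_occ_go * decay
  tag_occ_nogo <- tag_occ_nogo * decay
  if (!is.null(open)) {
    tag_go[, open] <- tag_go[, open] + drive
    tag_nogo[, !open] <- tag_nogo[, !open] + nogo_scale * drive
    tag_occ_go[open] <- tag_occ_go[open] + occupancy[open]
    tag_occ_nogo[!open] <- tag_occ_nogo[!open] +
      nogo_scale * occupancy[!open]
  }
  list(tag_go = tag_go, tag_nogo = tag_nogo,
       tag_occ_go = tag_occ_go, tag_occ_nogo = tag_occ_nogo)
}

#' Three-factor striatal weight update
#'
#' Opponent update gated by eligibility tags and dopamine. For synapses
#' tagged on the Go side (their gate opened), bursts move Go weights up and
#' NoGo weights down - making the flagged gating decision more likely - and
#' dips do the opposite. Synapses tagged on the NoGo side (their gate
#' stayed closed) learn with the opposite sign, with full weight under
#' dips - persistent failure while a gate is withheld pushes its Go
#' weights up, so a collapsed policy can be revived - but only
#' fractional weight (\code{burst_credit}) under bursts, since crediting
#' a non-action for success is weaker evidence. Weights clip to
#' [0, w_max]; untagged synapses never change.
#'
#' @param go_w,nogo_w Weight arrays (matching shapes).
#' @param tags Go-side eligibility tags (same shape, non-negative).
#' @param da Dopamine signal from \code{\link{dopamineSignal}}.
#' @param lr_w Learning rate.
#' @param w_max Weight ceiling.
#' @param tags_nogo NoGo-side eligibility tags (default none).
#' @param burst_credit Fraction of NoGo-side credit applied on bursts.
#' @return List with updated \code{go_w} and \code{nogo_w}.
#' @export
striatalThreeFactorUpdate <- function(go_w, nogo_w, tags, da, lr_w = 0.1,
                                      w_max = 1, tags_nogo = 0,
                                      burst_credit = 1) {
  d <- lr_w * da * (tags - (if (da < 0) 1 else burst_credit) * tags_nogo)
  list(go_w = pmin(pmax(go_w + d, 0), w_max),
       nogo_w = pmin(pmax(nogo_w - d, 0), w_max))
}

#' Delta-rule update of a plastic report mapping
#'
#' Supervised error-driven learning of the input-to-output and
#' PFC-to-output color mappings: \code{W <- W + lr * (target - produced)
#' pre'}. Zero error (or zero rate) leaves weights unchanged; repeated
#' training on a fixed pair drives the produced bump to the target.
#'
#' @param W Receiver-by-sender weight matrix.
#' @param pre Sender (pre-synaptic) activity vector.
#' @param produced Produced output activity (\code{W \%*\% pre}).
#' @param target Target output bump.
#' @param lr Learning rate.
#' @return Updated weight matrix.
#' @export
reportMappingUpdate <- function(W, pre, produced, target, lr = 0.5) {
  W + lr * tcrossprod(target - produced, pre)
}
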