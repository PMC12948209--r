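# Transform-recovery evaluation against phantom ground truth.

#' Per-slice transform recovery against phantom truth
#'
#' Compares the transforms recovered by \code{\link{stackDataset}} with the
#' inverses of the perturbations the phantom generator applied. The
#' reconstructed stack lives in an arbitrary rigid frame (the anchor
#' slice's observed frame), so the truth targets are expressed relative to
#' the anchor's perturbation and, additionally, the best-fit global rigid
#' offset between the recovered and true frames (the frame gauge, which no
#' registration can observe) is removed before judging per-slice
#' residuals.
#'
#' @param volume a \linkS4class{FeatureVolume} from
#'   \code{\link{stackDataset}}.
#' @param truth the \linkS4class{PhantomTruth} of the generating phantom.
#' @param anchor index (1-based) of the slice whose observed frame anchors
#'   the stack; defaults to the middle slice (the default stacking
#'   reference).
#' @return data.frame with per-slice residual rotation (deg) and
#'   translation magnitude (px) after gauge removal.
#' @export
transformRecovery <- function(volume, truth, anchor = NULL) {
  rec <- volume@transformsApplied
  P <- truth@transforms
  stopifnot(length(rec) == length(P))
  if (is.null(anchor)) anchor <- (length(P) + 1L) %/% 2L
  resid <- lapply(seq_along(rec), function(i) {
    target <- composeRigid(P[[anchor]], invertRigid(P[[i]]))
    composeRigid(rec[[i]], invertRigid(target))
  })
  # gauge: the componentwise median residual is a robust estimate of the
  # unobservable global frame offset (slices with failed registrations,
  # e.g. the tiny polar-cap sections, must not drag it)
  gTheta <- median(vapply(resid, function(r) r@thetaDeg, 1))
  gTx <- median(vapply(resid, function(r) r@txPx, 1))
  gTy <- median(vapply(resid, function(r) r@tyPx, 1))
  gauge <- invertRigid(RigidTransform2D(gTheta, gTx, gTy))
  resid <- lapply(resid, function(r) composeRigid(gauge, r))
  data.frame(
    z_index = seq_along(rec) - 1L,
    residual_theta_deg = vapply(resid, function(r) r@thetaDeg, 1),
    residual_trans_px = vapply(resid, function(r)
      sqrt(r@txPx^2 + r@tyPx^2), 1))
}
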