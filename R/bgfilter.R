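# Model-based background filtering (the BF core).
#
# Under the two-layer imaging model, the out-of-focus contribution of a raw
# frame is exactly D(k) * H_out / (H_in + H_out); subtracting its inverse
# transform is a fixed, parameter-free linear filter -- no data-dependent
# thresholding, which is what preserves weak signals and intensity linearity.

#' Background filter options
#'
#' Records how the 0/0 region outside the OTF support is handled. The
#' denominator of the background kernel vanishes beyond the cutoff; there the
#' kernel is defined as 0 (data outside the support are left untouched,
#' preserving their noise statistics for the downstream Wiener step) rather
#' than inflated with a regularizer.
#'
#' @param eps non-negative denominator regularizer (default 0 inside the
#'   support).
#' @param support_mask_rel_tol fraction of the DC value below which
#'   `|H_in + H_out|` is treated as zero.
#' @param clamp_negative default for clamping negative output values.
#' @export
filter_spec <- function(eps = 0, support_mask_rel_tol = 1e-6,
                        clamp_negative = FALSE) {
  stopifnot(eps >= 0, support_mask_rel_tol > 0, support_mask_rel_tol < 1)
  structure(list(eps = eps, support_mask_rel_tol = support_mask_rel_tol,
                 clamp_negative = clamp_negative),
            class = "filter_spec")
}

#' Build the Fourier-domain background filter
#'
#' `W(k) = H_out / (H_in + H_out + eps)` where `|H_in + H_out|` exceeds
#' `support_mask_rel_tol` times its DC value, and 0 elsewhere. On a symmetric
#' z grid W is real and bounded in \[0, 1\] (with `eps = 0`).
#'
#' @param otf an `otf_pair` from [split_otf()].
#' @param spec a [filter_spec()].
#' @return an object of class `background_filter` with the kernel `w` on the
#'   OTF grid.
#' @export
build_filter <- function(otf, spec = filter_spec()) {
  validate_otf_pair(otf)
  if (max(Mod(otf$h_in)) <= 0) stop("invalid optics: H_in identically zero")
  denom <- otf$h_in + otf$h_out
  dc <- Mod(denom[1, 1])
  support <- Mod(denom) > spec$support_mask_rel_tol * dc
  w <- matrix(0 + 0i, otf$shape[1], otf$shape[2])
  w[support] <- otf$h_out[support] / (denom[support] + spec$eps)
  if (max(Mod(otf$h_out)) <= spec$support_mask_rel_tol * dc) {
    warning("H_out is (near) zero: filter is identity-in-effect")
  }
  if (max(abs(Im(w))) <= 1e-9 * max(abs(Re(w)), 1e-300)) w <- Re(w)
  structure(list(w = w, shape = otf$shape, spec = spec,
                 k_cutoff_cycles_per_px = otf$k_cutoff_cycles_per_px),
            class = "background_filter")
}

#' @export
print.background_filter <- function(x, ...) {
  cat(sprintf("Background filter on %d x %d grid: W(0) = %.4f\n",
              x$shape[1], x$shape[2], Re(x$w[1, 1])))
  invisible(x)
}

#' Subtract the modeled out-of-focus background from one image
#'
#' Returns `d - iFt{Ft{d} . W}`, equivalently `iFt{Ft{d} . (1 - W)}`. The
#' operation is strictly linear and shift-invariant; no apodization window is
#' applied (periodic-grid contract shared with the simulator).
#'
#' @param d real image matching the filter grid.
#' @param filt a [background_filter()].
#' @param clamp_negative set negative output values to 0 after the
#'   subtraction; the clamped flux fraction is attached as attribute
#'   `clamped_flux`.
#' @export
filter_image <- function(d, filt, clamp_negative = filt$spec$clamp_negative) {
  stopifnot(inherits(filt, "background_filter"))
  if (!is.matrix(d) || !identical(as.integer(dim(d)), as.integer(filt$shape))) {
    stop("image shape does not match the filter grid")
  }
  if (any(!is.finite(d))) stop("input image contains NaN/Inf values")
  out_c <- ifft2(fft2(d) * (1 - filt$w))
  if (max(abs(Im(out_c))) > 1e-9 * max(abs(Re(out_c)), 1e-300)) {
    warning("non-negligible imaginary residue after filtering (asymmetric OTF?)")
  }
  out <- Re(out_c)
  if (clamp_negative) {
    neg <- sum(pmax(-out, 0))
    tot <- sum(abs(out))
    out[out < 0] <- 0
    attr(out, "clamped_flux") <- if (tot > 0) neg / tot else 0
  }
  out
}

#' Background-filter every frame of a raw stack
#'
#' The camera offset is subtracted first (a constant offset would otherwise
#' be scaled by `1 - W(0)`, corrupting intensity linearity), then
#' [filter_image()] is applied per frame.
#'
#' @param stack a [raw_sim_stack()].
#' @param filt a [background_filter()].
#' @param offset camera offset to remove before filtering.
#' @param clamp_negative see [filter_image()].
#' @return a [raw_sim_stack()] with filtered frames; `meta$filter` records
#'   provenance.
#' @export
filter_stack <- function(stack, filt, offset = 0, clamp_negative = FALSE) {
  stopifnot(inherits(stack, "raw_sim_stack"))
  d <- dim(stack$frames)
  out <- stack
  for (a in seq_len(d[3])) {
    for (p in seq_len(d[4])) {
      res <- tryCatch(
        filter_image(stack$frames[, , a, p] - offset, filt, clamp_negative),
        error = function(e) {
          stop(sprintf("frame (angle %d, phase %d): %s", a, p, conditionMessage(e)),
               call. = FALSE)
        })
      out$frames[, , a, p] <- res
    }
  }
  out$meta$filter <- list(w_dc = Re(filt$w[1, 1]), offset = offset,
                          clamp_negative = clamp_negative)
  out
}
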