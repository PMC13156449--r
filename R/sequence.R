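#' Interleaved 23Na/1H sequence parameters
#'
#' Defaults follow the interleaved dual-nuclear scheme: one 23Na excitation
#' every `TR_23Na = 60` ms (FA 82 deg, TE 1.15 ms) with two 1H excitations
#' (FA 10 deg) at alternating TRs of 13.08 and 20.76 ms filling the
#' remainder of each 60 ms unit.  Every 1H excitation is preceded by a
#' 10-sample k-space-centre (k0) navigator with 7.6 us dwell.
#'
#' @param TR_23Na,TE_23Na,FA_23Na sodium timing (ms) and flip angle (deg).
#' @param TR_1H alternating proton TRs (ms).
#' @param TE_1H,FA_1H proton echo time (ms) and flip angle (deg).
#' @param nav_samples,nav_dwell_us navigator samples and dwell.
#' @param na_samples,na_dwell_us sodium readout samples and dwell (us).
#' @param h_samples,h_dwell_us proton readout samples and dwell (us).
#' @param na_nominal_mm,h_nominal_mm nominal resolutions (mm).
#' @export
sequence_params <- function(TR_23Na = 60, TE_23Na = 1.15, FA_23Na = 82,
                            TR_1H = c(13.08, 20.76), TE_1H = 1.0,
                            FA_1H = 10, nav_samples = 10, nav_dwell_us = 7.6,
                            na_samples = 64, na_dwell_us = 25,
                            h_samples = 64, h_dwell_us = 10,
                            na_nominal_mm = 6, h_nominal_mm = 2) {
  stopifnot(TE_23Na < TR_23Na, nav_samples >= 1, all(TR_1H > 0),
            TR_23Na > sum(TR_1H))
  structure(list(TR_23Na = TR_23Na, TE_23Na = TE_23Na, FA_23Na = FA_23Na,
                 TR_1H = TR_1H, TE_1H = TE_1H, FA_1H = FA_1H,
                 nav_samples = nav_samples, nav_dwell_us = nav_dwell_us,
                 na_samples = na_samples, na_dwell_us = na_dwell_us,
                 h_samples = h_samples, h_dwell_us = h_dwell_us,
                 na_nominal_mm = na_nominal_mm, h_nominal_mm = h_nominal_mm),
            class = "sequence_params")
}

#' Acquisition timeline of the interleaved sequence
#'
#' One repeating 60 ms unit holds the 23Na excitation and readout followed
#' by two 1H excitations at the alternating TRs; every 1H event carries a
#' navigator.  Timestamps are absolute seconds from scan start.
#'
#' @param seq a [sequence_params()].
#' @param TA_s total acquisition time in seconds.
#' @return data.frame with columns `nucleus` ("23Na"/"1H") and `t` (s),
#'   strictly increasing.
#' @export
sequence_timeline <- function(seq, TA_s) {
  stopifnot(TA_s > 0)
  n_units <- floor(TA_s / (seq$TR_23Na * 1e-3) + 1e-9)
  unit_ms <- c(0, seq$TR_23Na - sum(seq$TR_1H),
               seq$TR_23Na - seq$TR_1H[2])
  starts <- (seq_len(n_units) - 1) * seq$TR_23Na * 1e-3
  t <- as.vector(outer(unit_ms * 1e-3, starts, "+"))
  nuc <- rep(c("23Na", "1H", "1H"), n_units)
  keep <- t < TA_s - 1e-12
  data.frame(nucleus = nuc[keep], t = t[keep])
}
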