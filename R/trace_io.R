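#' Two-channel intensity trace
#'
#' The pipeline's raw input: per-frame donor and acceptor photon counts for
#' one immobilized molecule, plus bleaching and illumination-check
#' metadata.
#'
#' @param trace_id identifier string.
#' @param time frame start times (s).
#' @param donor,acceptor photons/frame (same length as `time`).
#' @param donor_bleach_frame,acceptor_bleach_frame 1-based index of the
#'   first bleached frame, or `NA` when the dye survives the recording.
#' @param acceptor_present `TRUE` when the red-laser check frames confirm
#'   an acceptor dye.
#' @param single_pair `TRUE` when the molecule carries a single
#'   donor-acceptor pair.
#' @param direct_offset acceptor direct-excitation offset already
#'   subtracted from this trace (photons/frame; `NA` before correction).
#' @param frame_interval frame length (s).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(trace_id, time, donor, acceptor,
                            donor_bleach_frame = NA_integer_,
                            acceptor_bleach_frame = NA_integer_,
                            acceptor_present = TRUE, single_pair = TRUE,
                            direct_offset = NA_real_, frame_interval = 0.1) {
  n <- length(time)
  stop_if_not(length(donor) == n && length(acceptor) == n,
              "donor/acceptor must match time in length")
  stop_if_not(all(is.finite(donor)) && all(is.finite(acceptor)),
              "intensities must be finite")
  for (bf in list(donor_bleach_frame, acceptor_bleach_frame))
    stop_if_not(is.na(bf) || (bf >= 1 && bf <= n),
                "bleach frames must be within the trace")
  structure(list(trace_id = trace_id, time = as.numeric(time),
                 donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 donor_bleach_frame = donor_bleach_frame,
                 acceptor_bleach_frame = acceptor_bleach_frame,
                 acceptor_present = isTRUE(acceptor_present),
                 single_pair = isTRUE(single_pair),
                 direct_offset = direct_offset,
                 direct_fallback = FALSE,
                 frame_interval = frame_interval),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("Intensity trace", x$trace_id, "-", length(x$time), "frames;",
      "donor bleach:", x$donor_bleach_frame,
      "acceptor bleach:", x$acceptor_bleach_frame, "\n")
  invisible(x)
}

n_frames <- function(trace) length(trace$time)

#' Correction parameter set
#'
#' @param beta donor leakage fraction, in `[0, 0.5]`.
#' @param gamma detection-efficiency ratio (> 0), or `NA` when only
#'   apparent E is needed.
#' @param direct_offset per-trace acceptor direct-excitation offset
#'   (photons/frame).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(beta = 0.08, gamma = NA_real_,
                              direct_offset = NA_real_) {
  stop_if_not(beta >= 0 && beta <= 0.5, "beta must lie in [0, 0.5]")
  if (!is.na(gamma)) stop_if_not(gamma > 0, "gamma must be > 0")
  structure(list(beta = beta, gamma = gamma, direct_offset = direct_offset),
            class = "correction_params")
}

#' Write intensity traces as TSV plus a JSON metadata sidecar
#'
#' The TSV carries columns `trace_id`, `frame`, `time_s`, `donor`,
#' `acceptor`; bleach frames and flags go to the sidecar.
#'
#' @param traces list of [intensity_trace()] objects.
#' @param path TSV output path; the sidecar defaults to
#'   `<path>.meta.json`.
#' @param meta_path sidecar path override.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, meta_path = paste0(path, ".meta.json")) {
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, frame = seq_along(tr$time),
               time_s = tr$time, donor = tr$donor, acceptor = tr$acceptor)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(traces, function(tr)
    list(trace_id = tr$trace_id,
         donor_bleach_frame = tr$donor_bleach_frame,
         acceptor_bleach_frame = tr$acceptor_bleach_frame,
         acceptor_present = tr$acceptor_present,
         single_pair = tr$single_pair,
         direct_offset = tr$direct_offset,
         frame_interval = tr$frame_interval))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read intensity traces written by [write_traces()]
#'
#' @param path TSV path.
#' @param meta_path JSON sidecar path.
#' @return List of [intensity_trace()] objects.
#' @export
read_traces <- function(path, meta_path = paste0(path, ".meta.json")) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  meta_by_id <- setNames(meta, vapply(meta, `[[`, "", "trace_id"))
  ids <- unique(tab$trace_id)
  lapply(ids, function(id) {
    sub <- tab[tab$trace_id == id, ]
    m <- meta_by_id[[id]]
    tr <- intensity_trace(
      trace_id = id, time = sub$time_s, donor = sub$donor,
      acceptor = sub$acceptor,
      donor_bleach_frame = as.integer(m$donor_bleach_frame %||% NA_integer_),
      acceptor_bleach_frame = as.integer(m$acceptor_bleach_frame %||% NA_integer_),
      acceptor_present = m$acceptor_present %||% TRUE,
      single_pair = m$single_pair %||% TRUE,
      direct_offset = as.numeric(m$direct_offset %||% NA_real_),
      frame_interval = m$frame_interval %||% 0.1)
    tr
  })
}

#' Corrected FRET efficiency trace
#'
#' @param trace_id identifier.
#' @param time frame times (s).
#' @param e_fret apparent (or gamma-corrected) FRET efficiency per frame.
#' @param masked logical per frame; masked frames (post-bleach, zero-total)
#'   never enter downstream histograms or HMM fits.
#' @param params the [correction_params()] used.
#' @param gamma_corrected whether the gamma-corrected formula was used.
#' @param frame_interval frame length (s).
#' @return An object of class `fret_trace`.  Values outside `[-0.2, 1.2]`
#'   are flagged in the `outlier` field.
#' @export
fret_trace <- function(trace_id, time, e_fret, masked, params,
                       gamma_corrected = FALSE, frame_interval = 0.1) {
  stop_if_not(all(is.finite(e_fret[!masked])),
              "unmasked e_fret values must be finite")
  structure(list(trace_id = trace_id, time = time, e_fret = e_fret,
                 masked = masked,
                 outlier = !masked & (e_fret < -0.2 | e_fret > 1.2),
                 corrected_with = params,
                 gamma_corrected = gamma_corrected,
                 frame_interval = frame_interval),
            class = "fret_trace")
}

#' Unmasked FRET values of a trace
#' @param fret a [fret_trace()].
#' @return Numeric vector of usable per-frame efficiencies.
#' @export
fret_values <- function(fret) fret$e_fret[!fret$masked]
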