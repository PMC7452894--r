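fixtures_path <- function() {
  system.file("extdata", "fixtures.yaml", package = "scrunchFRET",
              mustWork = TRUE)
}

fixtures_raw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- yaml::read_yaml(fixtures_path())
    cache
  }
})

#' Packaged ground-truth parameter sets
#'
#' The package ships named kinetic schemes and photophysics sets whose state
#' FRET levels and (where printed) transition rates mirror the values
#' reported for the yeast mitochondrial initiation system: stalled
#' initiation complexes `"IC0"`, `"IC2"`, `"IC3"`, `"IC5"`--`"IC7"`, the
#' elongation complex `"EC8"`, the alternative labelling scheme
#' `"templ_11"`, washout fixtures `"washout_IC2"` / `"washout_IC7"`, the
#' post-washout branching fixture `"branching_IC7"`, and calibration sets
#' `"dna_only"` / `"gamma_cal"`.  2-aminopurine ensemble parameters are
#' available through [fixture_ensemble()].
#'
#' @param name fixture name; call with no argument to list available names.
#' @param phys which packaged photophysics variant to attach: `"default"`,
#'   `"longmovie"` (slow bleaching for long recordings) or `"nobleach"`.
#' @return For a valid `name`, a list with elements `scheme`
#'   ([kinetic_scheme()]), `phys` ([photophysics()]), `protocol`
#'   ([protocol()]) and `description`.  Without `name`, a character vector
#'   of fixture names.
#' @examples
#' fixtures()
#' fx <- fixtures("IC7")
#' scheme_fret_mean(fx$scheme, "scrunched")   # 0.811
#' scheme_rate(fx$scheme, "scrunched", "open")  # 0.0653
#' @export
fixtures <- function(name = NULL, phys = "default") {
  raw <- fixtures_raw()
  if (is.null(name)) return(names(raw$schemes))
  if (!name %in% names(raw$schemes))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(raw$schemes), collapse = ", "), call. = FALSE)
  fx <- raw$schemes[[name]]
  states <- do.call(rbind, lapply(fx$states, function(s)
    data.frame(label = s$label, fret_mean = s$fret_mean,
               fret_sd = s$fret_sd, stringsAsFactors = FALSE)))
  rates <- if (length(fx$rates)) {
    do.call(rbind, lapply(fx$rates, function(r)
      data.frame(from = r$from, to = r$to, rate = r$rate,
                 ntp = r$ntp %||% NA_character_, stringsAsFactors = FALSE)))
  } else NULL
  init <- as.numeric(fx$initial)
  init <- init / sum(init)
  scheme <- kinetic_scheme(states, rates, init)
  stop_if_not(phys %in% names(raw$photophysics),
              paste0("unknown photophysics variant '", phys, "'"))
  ph <- do.call(photophysics, raw$photophysics[[phys]])
  list(scheme = scheme, phys = ph,
       protocol = protocol(duration = fx$duration %||% 120,
                           frame_interval = 0.1),
       description = fx$description %||% name)
}

#' Packaged 2-aminopurine ensemble decay parameters
#'
#' Parameters of the bubble-collapse fluorescence decays observed when the
#' complex is walked to positions +7 through +10 (`"walk_7"` ... `"walk_10"`).
#' Decay rates are the printed values (0, 0.004, 0.0165, 0.0269 s^-1);
#' plateau levels are fixed non-printed choices.
#'
#' @param name ensemble name; call with no argument to list names.
#' @return List with elements `k` (s^-1), `f0`, `f_inf` (normalized
#'   fluorescence) and `duration` (s).
#' @export
fixture_ensemble <- function(name = NULL) {
  raw <- fixtures_raw()
  if (is.null(name)) return(names(raw$ensembles))
  if (!name %in% names(raw$ensembles))
    stop("unknown ensemble '", name, "'; available: ",
         paste(names(raw$ensembles), collapse = ", "), call. = FALSE)
  raw$ensembles[[name]]
}

#' Packaged photophysics variants
#'
#' @param name variant name (`"default"`, `"longmovie"`, `"nobleach"`).
#' @return A [photophysics()] object.
#' @export
fixture_photophysics <- function(name = "default") {
  raw <- fixtures_raw()
  stop_if_not(name %in% names(raw$photophysics),
              paste0("unknown photophysics variant '", name, "'; available: ",
                     paste(names(raw$photophysics), collapse = ", ")))
  do.call(photophysics, raw$photophysics[[name]])
}
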