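`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All error paths in the package raise conditions that subclass
#' `"birddog_error"`, so callers (and the CLI) can catch them selectively.
#'
#' @param class condition subclass, e.g. `"format_error"`.
#' @param fmt,... `sprintf()` message.
#' @noRd
bd_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "birddog_error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded simulation
#' helpers never perturb the global RNG stream.
#'
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by the scoring pipeline. Keys:
#' \describe{
#'   \item{confidence_threshold}{keypoints with confidence strictly below this
#'     are masked and interpolated (default 0.5).}
#'   \item{d_prime_floor}{floor applied to D' before `log(1/D')` so a
#'     perfectly stationary (synthetic) trial cannot produce `log(1/0)`
#'     (default 1e-6 body lengths/frame).}
#'   \item{dt_mode}{`"annotated"` (use recorded start/fall frames) or
#'     `"heuristic"` (detect posture onset and floor contact from keypoints).}
#'   \item{lift_margin_bl}{heuristic posture onset: extended wrist and ankle
#'     must clear the floor line by this many body lengths (default 0.1).}
#'   \item{floor_margin_bl}{heuristic fall: extended wrist or ankle within
#'     this many body lengths of the floor line (default 0.02).}
#'   \item{extension_angle_max}{heuristic posture onset: both limb-floor
#'     angles must be below this many degrees (default 30).}
#'   \item{task_cap_s}{task maximum in seconds; DT is capped here and frames
#'     beyond it are ignored (default 60).}
#' }
#'
#' @param ... overrides for individual keys.
#' @return named list of configuration values.
#' @export
#' @examples
#' birddog_config(confidence_threshold = 0.6)
birddog_config <- function(...) {
  cfg <- list(
    confidence_threshold = 0.5,
    d_prime_floor = 1e-6,
    dt_mode = "annotated",
    lift_margin_bl = 0.1,
    floor_margin_bl = 0.02,
    extension_angle_max = 30,
    task_cap_s = 60
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    bd_stop("config_error", "unknown configuration key(s): %s",
            paste(bad, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}
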