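# internal helpers shared across modules

.FA_EPS <- 1e-6
.P_FLOOR <- 1e-300

# clip to [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic child seed: split one global seed per dataset label so that
# adding a dataset never perturbs the streams of the others. Kept below 2^31.
.childSeed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 69621 + h * 10007 + 12345) %% 2147483647)
}

.stopIfNotPositive <- function(x, what) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("'", what, "' must be positive; offending value(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Fraction affected from viability readings
#'
#' Converts plate viability signal to the fraction affected used throughout
#' the median-effect arithmetic: `fa = 1 - treated/control`, computed per
#' plate against the vehicle control. Values implying `fa <= 0` (growth
#' stimulation) or `fa >= 1` are clipped into `[1e-6, 1 - 1e-6]` so the
#' median-effect inverse stays defined.
#'
#' @param treated numeric vector of treated-well signal (e.g. crystal-violet
#'   absorbance).
#' @param control positive scalar (or vector) vehicle-control signal.
#' @return Numeric vector of fractions affected in `(0, 1)`.
#' @examples
#' fractionAffected(c(80, 50, 20), control = 100)
#' @export
fractionAffected <- function(treated, control) {
  .stopIfNotPositive(control, "control")
  if (any(!is.finite(treated)))
    stop("'treated' must be finite")
  .clip(1 - treated / control, .FA_EPS, 1 - .FA_EPS)
}
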