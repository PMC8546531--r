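# Classed conditions so callers can distinguish bad files from bad arguments.

stop_gait <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("gaitbelt_", class), "gaitbelt_error")))
}

# shared argument checks ------------------------------------------------------

check_number <- function(x, name, positive = FALSE, class = "parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gait(sprintf("`%s` must be a single finite number", name), class)
  if (positive && x <= 0)
    stop_gait(sprintf("`%s` must be strictly positive (got %g)", name, x), class)
  invisible(x)
}

check_height <- function(height) {
  check_number(height, "height", class = "validation_error")
  if (height < 1.0 || height > 2.5)
    stop_gait(sprintf(
      "height must lie in [1.0, 2.5] m (got %g); heights entered in cm are rejected",
      height), "validation_error")
  invisible(height)
}

check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female"))
    stop_gait(sprintf("sex must be \"male\" or \"female\" (got \"%s\")",
                      paste(sex, collapse = ",")), "validation_error")
  invisible(sex)
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  check_number(seed, "seed")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
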