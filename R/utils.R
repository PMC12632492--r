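# Internal helpers shared across modules.

# Gas constant in kcal / (mol K).
.R_KCAL <- 1.98720425e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return RT in kcal/mol.
#' @examples
#' rt_kcal(320) # ~0.636
#' @export
rt_kcal <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop_lipiddta("`temperature` must be a single positive number (Kelvin)",
                  "input")
  .R_KCAL * temperature
}

# Classed error, so callers and tests can distinguish failure modes.
# class is one of: "config", "input", "degenerate", "estimation", "format".
stop_lipiddta <- function(msg, class = "input", call. = FALSE) {
  cnd <- errorCondition(msg,
                        class = c(paste0("lipiddta_", class, "_error"),
                                  "lipiddta_error"))
  stop(cnd)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_lipiddta("`seed` must be a single integer", "input")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Minimum-image wrap of in-plane displacements into [-L/2, L/2).
wrap_minimum_image <- function(x, box_length) {
  x - box_length * floor(x / box_length + 0.5)
}

# In-plane rotation by `angle` radians about the origin.
rotate_xy <- function(x, y, angle) {
  ca <- cos(angle); sa <- sin(angle)
  list(x = ca * x - sa * y, y = sa * x + ca * y)
}
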