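# let data.table's [ semantics apply to objects built inside this package
.datatable.aware <- TRUE

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normal-approximation CI multiplier; the conventional 1.96 at the default
# 95% level, qnorm otherwise
ci_z <- function(level = 0.95) {
  if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm((1 + level) / 2)
}

age_group_levels <- function() {
  c("0-17", "18-34", "35-44", "45-54", "55-64", ">=65")
}

#' Assign age-group labels
#'
#' Bins integer ages into the six study strata: 0-17, 18-34, 35-44, 45-54,
#' 55-64 and >=65 years. The bins partition `[0, Inf)`.
#'
#' @param age integer vector of ages in years (>= 0).
#' @return factor with the six age-group levels.
#' @export
age_group <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("ages must be non-negative")
  cut(age, breaks = c(-1, 17, 34, 44, 54, 64, Inf),
      labels = age_group_levels())
}

stratum_label <- function(age_group, sex) paste0(age_group, "/", sex)
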