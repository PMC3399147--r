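#' The 13-parameter uncertain space of the vegetation model
#'
#' Returns the table of the thirteen sampled model parameters: name,
#' standard (default) value, lower and upper bound of the uniform sampling
#' range, and a short description. All parameters are treated as independent
#' uniform random variables on \[lower, upper\].
#'
#' The printed source range for `k_mort1` is degenerate (\[0.01, 0.01\]),
#' which would make the parameter unsampleable even though it demonstrably
#' influences the model output. The loader therefore repairs it to a range
#' bracketing the standard value and warns; pass `k_mort1_range` to override.
#'
#' @param k_mort1_range length-2 numeric, replacement range for `k_mort1`.
#'   The default `c(0.01, 0.1)` brackets the standard value 0.05.
#' @param quiet suppress the repair warning.
#'
#' @return A data.frame with one row per parameter and columns
#'   `name`, `standard`, `lower`, `upper`, `description`, in a fixed
#'   documented order (the order below is the column order used by
#'   [lhs_sample()] and all downstream sensitivity output).
#' @export
#' @examples
#' p <- default_parameter_table(quiet = TRUE)
#' p[p$name == "k_beer", ]
default_parameter_table <- function(k_mort1_range = c(0.01, 0.1), quiet = FALSE) {
  path <- system.file("extdata", "parameter_table.csv", package = "vegens",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 13L)
  i <- match("k_mort1", tab$name)
  if (tab$lower[i] == tab$upper[i]) {
    stopifnot(is.numeric(k_mort1_range), length(k_mort1_range) == 2L,
              k_mort1_range[1] < k_mort1_range[2])
    if (!quiet) {
      warning(sprintf(
        "k_mort1 ships with a degenerate range [%g, %g]; repaired to [%g, %g]",
        tab$lower[i], tab$upper[i], k_mort1_range[1], k_mort1_range[2]),
        call. = FALSE)
    }
    tab$lower[i] <- k_mort1_range[1]
    tab$upper[i] <- k_mort1_range[2]
  }
  validate_parameter_table(tab)
  tab
}

validate_parameter_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "standard", "lower", "upper") %in% names(tab)),
            !anyDuplicated(tab$name))
  if (any(tab$lower >= tab$upper)) {
    bad <- tab$name[tab$lower >= tab$upper]
    stop("degenerate parameter range for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # standard must lie inside its sampling range (boundary allowed, e.g. k_rp)
  off <- tab$standard < tab$lower | tab$standard > tab$upper
  if (any(off)) {
    stop("standard value outside range for: ",
         paste(tab$name[off], collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Named vector of standard (control) parameter values
#'
#' @inheritParams lhs_sample
#' @return named numeric vector of length 13.
#' @export
standard_parameters <- function(specs = default_parameter_table(quiet = TRUE)) {
  stats::setNames(specs$standard, specs$name)
}

#' Stratified Latin hypercube sample of the parameter space
#'
#' Draws `n` realizations of the parameter vector by Latin hypercube
#' sampling: each parameter's range is divided into `n` equal-probability
#' (here equal-width, since all marginals are uniform) strata, one value is
#' drawn uniformly *within* each stratum, and the per-parameter values are
#' then paired across parameters by independent uniform random permutations.
#' Every column therefore contains exactly one value per stratum, and no
#' cross-parameter correlation is imposed.
#'
#' @param specs parameter table as from [default_parameter_table()].
#' @param n number of samples (= number of strata per parameter), >= 1.
#' @param seed integer seed; the draw is fully reproducible given
#'   `(specs, n, seed)`.
#' @return An object of class `lhs_sample`: a list with `values`
#'   (`n` x `k` numeric matrix, columns named by parameter), `param_names`,
#'   `seed`, and `sample_ids` (`1:n`).
#' @export
#' @examples
#' s <- lhs_sample(default_parameter_table(quiet = TRUE), n = 10, seed = 1)
#' dim(s$values)
lhs_sample <- function(specs, n, seed) {
  validate_parameter_table(specs)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  k <- nrow(specs)
  vals <- matrix(NA_real_, n, k, dimnames = list(NULL, specs$name))
  with_local_seed(seed, {
    for (j in seq_len(k)) {
      lo <- specs$lower[j]
      wid <- (specs$upper[j] - specs$lower[j]) / n
      # one uniform draw inside each stratum, then random pairing
      strat <- lo + (seq_len(n) - 1 + stats::runif(n)) * wid
      vals[, j] <- strat[sample.int(n)]
    }
  })
  structure(
    list(values = vals, param_names = specs$name, seed = as.integer(seed),
         sample_ids = seq_len(n)),
    class = "lhs_sample")
}

#' @export
print.lhs_sample <- function(x, ...) {
  cat(sprintf("Latin hypercube sample: %d x %d (seed %d)\n",
              nrow(x$values), ncol(x$values), x$seed))
  invisible(x)
}

#' Check Latin hypercube stratum occupancy
#'
#' Verifies, per parameter, that a sample matrix contains exactly one value
#' in each of the `n` equal-width strata of that parameter's range. Strata
#' are half-open `[a, b)` with the final stratum closed at the upper bound.
#'
#' @param sample an [lhs_sample()] result, or a plain numeric matrix.
#' @param specs parameter table aligned with the matrix columns.
#' @return list with `pass` (logical scalar), `column_pass` (per parameter),
#'   and `offending` (per parameter, integer indices of strata whose
#'   occupancy is not exactly one).
#' @export
check_stratification <- function(sample, specs) {
  vals <- if (inherits(sample, "lhs_sample")) sample$values else sample
  stopifnot(is.matrix(vals))
  if (ncol(vals) != nrow(specs))
    stop("matrix has ", ncol(vals), " columns but ", nrow(specs),
         " parameter specs", call. = FALSE)
  n <- nrow(vals)
  column_pass <- logical(ncol(vals))
  offending <- vector("list", ncol(vals))
  names(column_pass) <- names(offending) <- specs$name
  for (j in seq_len(ncol(vals))) {
    wid <- (specs$upper[j] - specs$lower[j]) / n
    idx <- floor((vals[, j] - specs$lower[j]) / wid) + 1
    idx[vals[, j] >= specs$upper[j]] <- n  # closed final stratum
    occ <- tabulate(idx[idx >= 1 & idx <= n], nbins = n)
    bad <- which(occ != 1L)
    column_pass[j] <- length(bad) == 0L &&
      all(vals[, j] >= specs$lower[j]) && all(vals[, j] <= specs$upper[j])
    offending[[j]] <- bad
  }
  list(pass = all(column_pass), column_pass = column_pass,
       offending = offending)
}

# Run code under a temporary RNG state so package draws do not disturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Documented per-stage seed derivation: stages get distinct, reproducible
# substreams of a master seed, kept below 2^31 - 1.
derive_seed <- function(master, stage) {
  stage_index <- match(stage, c("sample", "climate", "simulate", "control",
                                "prcc", "uncertainty", "noise"))
  if (is.na(stage_index)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.double(master) * 48271 + stage_index * 9973) %% 2147483647)
}
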