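# analytic SD of a standard normal truncated at +/- 2
TRUNC2_SD <- sqrt(1 - 4 * stats::dnorm(2) / (stats::pnorm(2) - stats::pnorm(-2)))

#' Truncated standard normal deviates with unit standard deviation
#'
#' Draws from a standard normal truncated at +/-2 (so extreme deviates that
#' could flip the sign of a simulated function are excluded), rescaled by
#' the analytic standard deviation of the truncated law (~0.8796) so the
#' returned variate has standard deviation exactly 1. The support is
#' therefore contained in [-2.274, 2.274].
#'
#' @param n Number of deviates.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_std_normal <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- rnorm(max(n - length(out), 16))
    out <- c(out, z[abs(z) <= 2])
  }
  out[seq_len(n)] / TRUNC2_SD
}

#' Configuration of a virtual biodiversity dataset
#'
#' Describes the hidden functional structure and the observation design of a
#' simulated biodiversity-ecosystem-functioning experiment: species are
#' partitioned into true functional groups, each of the `2^sigma - 1`
#' possible assembly motifs receives a mean function drawn uniformly on
#' `mean_interval`, and each assembled ecosystem observes its motif mean
#' distorted by multiplicative truncated-normal noise of relative error
#' `cv`.
#'
#' @param group_sizes Integer vector (all >= 1): sizes of the true
#'   functional groups; species count is `sum(group_sizes)`.
#' @param mean_interval Length-2 numeric `(low, high)`, in the units of the
#'   simulated ecosystem function.
#' @param cv Relative error (coefficient of variation) of the noise, >= 0.
#' @param design `"full_factorial"` (all possible species combinations) or
#'   `"sample"` (a uniform without-replacement sample of combinations).
#' @param sample_size Number of ecosystems drawn when `design = "sample"`.
#' @param include_monocultures Should single-species ecosystems be eligible?
#' @param seed Integer seed recorded and used by [generate_dataset()];
#'   `NULL` leaves the RNG state untouched.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(group_sizes, mean_interval, cv,
                              design = c("full_factorial", "sample"),
                              sample_size = NULL,
                              include_monocultures = TRUE,
                              seed = NULL) {
  design <- match.arg(design)
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) < 1 || any(group_sizes < 1)) {
    abort("`group_sizes` must all be >= 1.")
  }
  s <- sum(group_sizes)
  if (s > 30) abort("At most 30 species are supported.")
  if (length(mean_interval) != 2 || mean_interval[1] >= mean_interval[2]) {
    abort("`mean_interval` must be (low, high) with low < high.")
  }
  if (cv < 0) abort("`cv` must be >= 0.")
  n_eligible <- 2^s - 1 - if (include_monocultures) 0 else s
  if (design == "sample") {
    if (is.null(sample_size)) abort("`sample_size` is required for design = 'sample'.")
    if (sample_size > n_eligible) {
      abort(sprintf(
        "`sample_size` (%d) exceeds the %d eligible combinations.",
        sample_size, n_eligible
      ))
    }
  }
  structure(
    list(
      group_sizes = group_sizes, s = s,
      sigma = length(group_sizes),
      mean_interval = as.numeric(mean_interval), cv = cv,
      design = design, sample_size = sample_size,
      include_monocultures = include_monocultures, seed = seed
    ),
    class = "simulation_config"
  )
}

# presence matrix (one row per code) from composition bit codes
decode_presence <- function(codes, s) {
  P <- vapply(
    seq_len(s) - 1L,
    function(b) as.double(bitwAnd(codes, bitwShiftL(1L, b)) > 0),
    numeric(length(codes))
  )
  matrix(P, nrow = length(codes), ncol = s)
}

#' Generate a virtual biodiversity dataset
#'
#' Assembles the observation design (all combinations, or a random sample of
#' them), then draws one mean function per possible assembly motif
#' (uniformly on the configured interval, for all `2^sigma - 1` motifs
#' whether observed or not), and finally the observed function of each
#' ecosystem as `F = mean * (1 + cv * z)` with `z` a unit-variance
#' truncated standard normal ([rtrunc_std_normal()]). Motif means are drawn
#' independently, so distinct motifs may collide; that is a legitimate (and
#' hard) feature of the generated data. Everything is deterministic given
#' the seed; means and errors are re-drawn after each design sampling.
#'
#' @param config A [simulation_config()].
#' @return A list of class `virtual_dataset`: `sample` (an [eco_sample()]),
#'   `true_partition` (named canonical partition), `motif_means` (tibble of
#'   all possible motifs and their drawn means), `config`.
#' @export
#' @examples
#' cfg <- simulation_config(c(1, 2, 3), c(0.4, 1.4), cv = 0.08, seed = 42)
#' vd <- generate_dataset(cfg)
#' n_ecosystems(vd$sample) # 63: all 2^6 - 1 combinations
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$s
  sigma <- config$sigma
  g_true <- rep(seq_len(sigma), config$group_sizes)

  all_codes <- seq_len(2^s - 1)
  if (!config$include_monocultures) {
    all_codes <- all_codes[!all_codes %in% bitwShiftL(1L, seq_len(s) - 1L)]
  }
  codes <- if (config$design == "sample") {
    sort(sample(all_codes, config$sample_size))
  } else {
    all_codes
  }
  P <- decode_presence(codes, s)

  # one mean per possible motif, observed or not
  motif_means <- runif(2^sigma - 1, config$mean_interval[1], config$mean_interval[2])
  group_bit <- 2^(seq_len(sigma) - 1)
  Gind <- matrix(0, s, sigma)
  Gind[cbind(seq_len(s), g_true)] <- 1
  motif_code <- as.integer(((P %*% Gind) > 0) %*% group_bit)
  mu <- motif_means[motif_code]
  F <- mu * (1 + config$cv * rtrunc_std_normal(length(mu)))

  species <- sprintf("sp%02d", seq_len(s))
  ids <- sprintf("eco%05d", codes)
  sample <- new_eco_sample(
    presence = P, function_values = F,
    species = species, ecosystem_ids = ids
  )
  motif_tbl <- tibble::tibble(
    motif_code = seq_len(2^sigma - 1),
    motif = vapply(
      seq_len(2^sigma - 1),
      function(code) paste(which(bitwAnd(code, group_bit) > 0), collapse = "+"),
      character(1)
    ),
    mean_function = motif_means
  )
  structure(
    list(
      sample = sample,
      true_partition = stats::setNames(canonicalize_partition(g_true), species),
      motif_means = motif_tbl,
      config = config
    ),
    class = "virtual_dataset"
  )
}

#' @export
print.virtual_dataset <- function(x, ...) {
  cat(sprintf(
    "<virtual_dataset> %d ecosystems, %d species in %d true groups (%s), cv = %g\n",
    n_ecosystems(x$sample), x$config$s, x$config$sigma,
    paste(x$config$group_sizes, collapse = "/"), x$config$cv
  ))
  invisible(x)
}

#' Number of pluri-species combinations of s species
#'
#' All non-empty species combinations except the monocultures:
#' `2^s - 1 - s`.
#'
#' @param s Number of species (>= 2).
#' @return An integer (as double for large s).
#' @export
#' @examples
#' count_pluri_combinations(16) # 65519
count_pluri_combinations <- function(s) {
  if (any(s < 2)) abort("`s` must be at least 2.")
  2^s - 1 - s
}

#' Number of possible assembly motifs of sigma functional groups
#'
#' Every non-empty combination of functional groups is a possible motif:
#' `2^sigma - 1`.
#'
#' @param sigma Number of functional groups (>= 1).
#' @return An integer (as double for large sigma).
#' @export
#' @examples
#' count_motifs(3) # 7
count_motifs <- function(sigma) {
  if (any(sigma < 1)) abort("`sigma` must be at least 1.")
  2^sigma - 1
}
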