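#' Build an ecosystem sample from a composition table
#'
#' An ecosystem sample couples a binary species presence/absence matrix with
#' one observed ecosystem function value per ecosystem (e.g. substrate
#' oxidation, aboveground biomass). It is the input of every fitting
#' operation in the package.
#'
#' @param data A data frame: one row per ecosystem, one id column, one
#'   numeric function column, and one strictly binary (0/1) column per
#'   species. Replicated compositions (identical rows up to the id) are
#'   legal and expected in designed experiments.
#' @param id_col Name or index of the ecosystem-id column. Default: first
#'   column.
#' @param function_col Name or index of the observed-function column.
#'   Default: last column.
#'
#' @return An object of class `eco_sample`, a list with elements
#'   `presence` (n x s integer matrix), `function_values` (length-n numeric),
#'   `species` (character), `ecosystem_ids` (character).
#' @details Validation enforces: unique species names and ecosystem ids,
#'   strictly binary presence cells, at least one species present in every
#'   ecosystem, and finite function values. Abundances are rejected rather
#'   than thresholded: the model only uses composition.
#' @export
#' @examples
#' toy <- eco_sample(tibble::tibble(
#'   id = paste0("e", 1:5),
#'   X = c(1, 1, 1, 0, 1), Y = c(0, 1, 0, 1, 1), Z = c(0, 0, 1, 1, 1),
#'   f = c(10, 20, 24, 8, 22)
#' ))
#' toy
eco_sample <- function(data, id_col = 1L, function_col = ncol(data)) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (nrow(data) < 1L) abort("`data` must contain at least one ecosystem.")
  id_col <- col_index(data, id_col, "id_col")
  function_col <- col_index(data, function_col, "function_col")
  sp_cols <- setdiff(seq_along(data), c(id_col, function_col))
  if (length(sp_cols) < 1L) abort("`data` contains no species columns.")

  ids <- as.character(data[[id_col]])
  fv <- data[[function_col]]
  if (!is.numeric(fv)) abort("Function column must be numeric.")
  pres <- as.matrix(data[sp_cols])
  storage.mode(pres) <- "double"

  bad <- which(!(pres %in% c(0, 1)) | is.na(pres))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(pres)) + 1
    j <- ((bad[1] - 1) %/% nrow(pres)) + 1
    abort(sprintf(
      "Presence values must be 0 or 1; found `%s` at row %d ('%s'), column '%s'.",
      format(pres[bad[1]]), i, ids[i], colnames(pres)[j]
    ))
  }
  new_eco_sample(
    presence = pres, function_values = as.numeric(fv),
    species = colnames(pres), ecosystem_ids = ids
  )
}

new_eco_sample <- function(presence, function_values, species, ecosystem_ids) {
  if (anyDuplicated(species)) abort("Species names must be unique.")
  if (anyDuplicated(ecosystem_ids)) {
    abort(sprintf(
      "Ecosystem ids must be unique (duplicated: '%s').",
      ecosystem_ids[anyDuplicated(ecosystem_ids)]
    ))
  }
  if (any(!is.finite(function_values))) {
    abort("All function values must be finite.")
  }
  empty <- rowSums(presence) == 0
  if (any(empty)) {
    abort(sprintf(
      "Every ecosystem must contain at least one species; row '%s' is empty.",
      ecosystem_ids[which(empty)[1]]
    ))
  }
  storage.mode(presence) <- "double"
  dimnames(presence) <- list(ecosystem_ids, species)
  structure(
    list(
      presence = presence,
      function_values = function_values,
      species = species,
      ecosystem_ids = ecosystem_ids
    ),
    class = "eco_sample"
  )
}

col_index <- function(data, col, what) {
  if (is.character(col)) {
    idx <- match(col, names(data))
    if (is.na(idx)) abort(sprintf("`%s` ('%s') is not a column of `data`.", what, col))
    return(idx)
  }
  col <- as.integer(col)
  if (col < 1L || col > ncol(data)) abort(sprintf("`%s` out of range.", what))
  col
}

#' @export
print.eco_sample <- function(x, ...) {
  cat(sprintf(
    "<eco_sample> %d ecosystems x %d species\n", n_ecosystems(x), n_species(x)
  ))
  cat(
    "  species:", paste(head(x$species, 8), collapse = ", "),
    if (n_species(x) > 8) "...", "\n"
  )
  cat(sprintf(
    "  function: mean %.4g, range [%.4g, %.4g]\n",
    mean(x$function_values), min(x$function_values), max(x$function_values)
  ))
  invisible(x)
}

#' Number of ecosystems / species in a sample
#' @param sample An [eco_sample()].
#' @return An integer scalar.
#' @export
n_ecosystems <- function(sample) nrow(sample$presence)

#' @rdname n_ecosystems
#' @export
n_species <- function(sample) ncol(sample$presence)

#' @export
as_tibble.eco_sample <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(ecosystem_id = x$ecosystem_ids),
    tibble::as_tibble(x$presence),
    tibble::tibble(function_value = x$function_values)
  )
}

#' Read / write an ecosystem composition table
#'
#' The on-disk format is a plain CSV with a header: one id column, one
#' numeric function column and binary species columns. By default the first
#' column is the id and the last the function; both can be remapped.
#'
#' @param path File path.
#' @param id_col,function_col Column roles, as in [eco_sample()].
#' @return `read_eco_sample()` returns an [eco_sample()];
#'   `write_eco_sample()` returns `path` invisibly. The pair round-trips a
#'   valid sample exactly (values and ordering).
#' @export
read_eco_sample <- function(path, id_col = 1L, function_col = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  eco_sample(df, id_col = id_col, function_col = function_col %||% ncol(df))
}

#' @param sample An [eco_sample()].
#' @rdname read_eco_sample
#' @export
write_eco_sample <- function(sample, path) {
  stopifnot(inherits(sample, "eco_sample"))
  df <- as_tibble(sample)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
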