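# Embedded catalog of per-receptor Hill characterizations of ATP
# dose-response curves, transcribed from published heterologous-expression
# studies (electrophysiology, cytosolic Ca2+ or IP3 readouts). Each row is
# one receptor/species characterization; non-responsive entries (no ATP
# response reported) carry no numeric parameters. `species` is the query tag
# ("human", "rodent", "bovine"); `source_species` records the species as
# printed in the source ("rat", "mouse", "rodent", ...). Bovine P2Y12 and
# human P2Y13 stand in for missing rodent data (surrogate = TRUE).

.catalog_rows <- function() {
  r <- function(receptor, species, source_species, k, kerr, h, herr, r2,
                source, responsive = TRUE, surrogate = FALSE) {
    data.frame(receptor = receptor, species = species,
               source_species = source_species,
               k_half_M = k, k_half_err_M = kerr,
               hill = h, hill_err = herr, r2 = r2,
               responsive = responsive, surrogate_species = surrogate,
               source = source, stringsAsFactors = FALSE)
  }
  na <- NA_real_
  do.call(rbind, list(
    r("P2X1", "human",  "human", 1.3e-6, 0.3e-6, 0.8, 0.2, 0.97, "Allsopp et al. 2011"),
    r("P2X1", "rodent", "rat",   8.2e-7, 0.8e-7, 4.4, 0.9, 0.99, "Le et al. 1998"),
    r("P2X2", "human",  "human", 1.2e-5, 0.2e-5, 1.1, 0.2, 0.99, "Roberts et al. 2008"),
    r("P2X2", "rodent", "rat",   8.2e-6, 0.1e-6, 1.3, 0.3, 0.99, "Boue-Grabot et al. 2000"),
    r("P2X3", "human",  "human", 5.2e-7, 0.6e-7, 1.1, 0.1, 0.97, "Garcia-Guzman et al. 1997a"),
    r("P2X3", "rodent", "rat",   3.4e-7, 0.6e-7, 1.2, 0.2, 0.99, "Lewis et al. 1995"),
    r("P2X4", "human",  "human", 7.4e-6, 0.4e-6, 1.4, 0.1, 0.99, "Garcia-Guzman et al. 1997b"),
    r("P2X4", "rodent", "rat",   1.1e-5, 0.1e-5, 1.3, 0.2, 0.99, "Garcia-Guzman et al. 1997b"),
    r("P2X5", "human",  "human", 4.5e-6, 0.1e-6, 1.5, 0.1, 0.99, "Bo et al. 2003"),
    r("P2X5", "rodent", "rodent", 7.8e-6, 0.5e-6, 1.3, 0.1, 0.99, "Garcia-Guzman et al. 1996"),
    r("P2X6", "human",  "human", na, na, na, na, na,
      "North 2002 (no currents evoked by ATP)", responsive = FALSE),
    r("P2X6", "rodent", "rat", na, na, na, na, na,
      "Roberts et al. 2006 (no functional homotrimeric channels)", responsive = FALSE),
    r("P2X7", "human",  "human", 1.9e-3, 0.3e-3, 2.0, 0.4, 0.99, "Roger et al. 2010"),
    r("P2X7", "rodent", "rat",   1.3e-4, 0.3e-4, 2.2, 0.8, 0.97, "Surprenant et al. 1996"),
    r("P2Y1", "human",  "human", 3.0e-7, 0.3e-7, 0.9, 0.1, 0.99, "Palmer et al. 1998"),
    r("P2Y1", "rodent", "rat",   3e-7,   1e-7,   0.5, 0.1, 0.97, "Vohringer et al. 2000"),
    r("P2Y2", "human",  "human", 2.0e-7, 0.4e-7, 1.2, 0.3, 0.98, "Nicholas et al. 1996"),
    r("P2Y2", "rodent", "rat",   2.9e-6, 0.4e-6, 1.4, 0.2, 0.99, "Wildman et al. 2003"),
    r("P2Y4", "human",  "human", 2.9e-5, 0.2e-5, 1.3, 0.1, 0.99, "Nicholas et al. 1996"),
    r("P2Y4", "rodent", "rat",   1.2e-6, 0.2e-6, 1.0, 0.2, 0.99, "Wildman et al. 2003"),
    r("P2Y6", "human",  "human", na, na, na, na, na,
      "Nicholas et al. 1996 (no significant ATP sensitivity)", responsive = FALSE),
    r("P2Y6", "rodent", "mouse", na, na, na, na, na,
      "Lazarowski et al. 2001 (no significant ATP sensitivity)", responsive = FALSE),
    r("P2Y11", "human", "human", 2.5e-6, 0.1e-6, 1.1, 0.1, 0.99, "Qi et al. 2001"),
    r("P2Y11", "rodent", "rodent", na, na, na, na, na,
      "von Kugelgen 2006 (transcripts not found in rat or mouse)", responsive = FALSE),
    r("P2Y12", "human", "human", na, na, na, na, na,
      "von Kugelgen 2006 (no significant ATP sensitivity)", responsive = FALSE),
    r("P2Y12", "rodent", "bovine", 3.7e-6, 0.7e-6, 0.8, 0.1, 0.99,
      "Ennion et al. 2004 (bovine surrogate)", surrogate = TRUE),
    r("P2Y13", "human", "human", 5e-6, 2e-6, 1.2, 0.4, 0.97, "Marteau et al. 2003"),
    r("P2Y13", "rodent", "human", 5e-6, 2e-6, 1.2, 0.4, 0.97,
      "Marteau et al. 2003 (human surrogate; rat P2Y13 not ATP-sensitive)",
      surrogate = TRUE),
    r("P2Y14", "human", "human", na, na, na, na, na,
      "Chambers et al. 2000 (no significant ATP sensitivity)", responsive = FALSE),
    r("P2Y14", "rodent", "rodent", na, na, na, na, na,
      "von Kugelgen 2006 (no significant ATP sensitivity)", responsive = FALSE)
  ))
}

#' The embedded P2 receptor catalog
#'
#' Returns the full per-receptor Hill-parameter catalog as a data frame with
#' one row per receptor/species characterization. Central values
#' (`k_half_M`, `hill`) parameterize basis functions; the `*_err` columns
#' carry the published 95% uncertainties for optional Monte-Carlo
#' propagation. Non-responsive entries (`responsive = FALSE`) have `NA`
#' numeric parameters.
#'
#' @return a `data.frame` with columns `receptor`, `species`,
#'   `source_species`, `k_half_M`, `k_half_err_M`, `hill`, `hill_err`, `r2`,
#'   `responsive`, `surrogate_species`, `source`.
#' @export
receptor_catalog <- function() {
  df <- .catalog_rows()
  rownames(df) <- NULL
  df
}

#' Look up one receptor's Hill characterization
#'
#' @param name receptor identifier, e.g. `"P2Y1"`, `"P2X7"`.
#' @param species query species tag: `"human"` or `"rodent"` (rodent resolves
#'   rat/mouse source entries, plus the documented bovine/human surrogates
#'   for P2Y12/P2Y13).
#' @return a one-row data frame of class `receptor_params`.
#' @export
get_receptor <- function(name, species = c("rodent", "human")) {
  species <- match.arg(species)
  cat_df <- receptor_catalog()
  hit <- cat_df[cat_df$receptor == name & cat_df$species == species, ,
                drop = FALSE]
  if (nrow(hit) != 1L) {
    avail <- paste(sprintf("%s/%s", cat_df$receptor, cat_df$species),
                   collapse = ", ")
    abort_catalog(sprintf(
      "no catalog entry for %s/%s; available: %s", name, species, avail))
  }
  class(hit) <- c("receptor_params", "data.frame")
  hit
}

#' Assemble a basis set of receptors
#'
#' A basis set is an ordered collection of ATP-responsive receptor
#' characterizations whose Hill curves serve as fixed basis functions for
#' ensemble decomposition.
#'
#' @param names character vector of receptor identifiers (unique).
#' @param species query species tag.
#' @return an object of class `basis_set` (a data frame of catalog rows).
#' @export
basis_set <- function(names, species = c("rodent", "human")) {
  species <- match.arg(species)
  if (anyDuplicated(names)) abort_catalog("basis receptor names must be unique")
  rows <- lapply(names, get_receptor, species = species)
  df <- do.call(rbind, rows)
  if (any(!df$responsive)) {
    abort_catalog(sprintf(
      "non-ATP-responsive receptor(s) cannot enter a basis: %s",
      paste(df$receptor[!df$responsive], collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("basis_set", "data.frame")
  df
}

#' Osteoblast P2 receptor basis
#'
#' The ATP-responsive P2 receptors expressed on osteoblasts: P2X2, P2X5,
#' P2X7, P2Y1, P2Y2, P2Y4. P2X6 and P2Y6 are also expressed but are not
#' ATP-responsive and are excluded.
#'
#' @param species query species tag (`"rodent"` for murine osteoblastic
#'   MC3T3-E1 work).
#' @return a `basis_set` of 6 receptors.
#' @export
osteoblast_basis <- function(species = c("rodent", "human")) {
  basis_set(c("P2X2", "P2X5", "P2X7", "P2Y1", "P2Y2", "P2Y4"),
            species = match.arg(species))
}

#' Evaluate a basis set over concentrations
#'
#' @param basis a `basis_set`.
#' @param concentrations numeric vector of molar concentrations (>= 0).
#' @return numeric matrix, one column per basis member in basis order
#'   (named by receptor), entries = that member's Hill response.
#' @export
evaluate_basis <- function(basis, concentrations) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(concentrations) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = nrow(basis),
                  dimnames = list(NULL, basis$receptor)))
  }
  cols <- lapply(seq_len(nrow(basis)), function(i) {
    hill_response(concentrations, basis$k_half_M[i], basis$hill[i])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- basis$receptor
  m
}

#' Export / import the catalog as JSON
#'
#' The catalog round-trips bit-exactly through this serialization (doubles
#' are written at full precision).
#'
#' @param path file path for the JSON catalog.
#' @param catalog the catalog data frame to serialize.
#' @return `write_catalog_json()` returns the path invisibly;
#'   `read_catalog_json()` returns the catalog data frame.
#' @export
write_catalog_json <- function(path, catalog = receptor_catalog()) {
  js <- jsonlite::toJSON(catalog, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  num <- c("k_half_M", "k_half_err_M", "hill", "hill_err", "r2")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  df$responsive <- as.logical(df$responsive)
  df$surrogate_species <- as.logical(df$surrogate_species)
  df[, names(receptor_catalog()), drop = FALSE]
}

#' @export
print.basis_set <- function(x, ...) {
  cat("P2 receptor basis set (", nrow(x), " members, species = ",
      x$species[1L], ")\n", sep = "")
  print.data.frame(x[, c("receptor", "source_species", "k_half_M", "hill")],
                   row.names = FALSE)
  invisible(x)
}
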