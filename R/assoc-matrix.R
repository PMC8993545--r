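#' Drug-drug association matrix
#'
#' A symmetric drug-by-drug similarity matrix for one association type. Scores
#' live in `[0, 1]`; a pair absent from the source scores 0 (the missing-data
#' convention used throughout the package). Self-scores are stored but never
#' consulted when building features: a drug is never compared with itself.
#'
#' @param m Square numeric matrix with identical row and column names (the
#'   drug identifiers).
#' @param type Association type tag: `"f"` (fingerprint), `"s"` (structure),
#'   `"a"` (ATC code), `"tm"` (text mining), `"t"` (target protein).
#' @return The matrix with class `assoc_matrix` and a `type` attribute.
#' @export
assoc_matrix <- function(m, type) {
  type <- match.arg(type, ASSOC_TYPES)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix")
  if (nrow(m) != ncol(m)) abort("association matrix must be square")
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m)) || !identical(ids, colnames(m))) {
    abort("row and column names must be identical drug ids")
  }
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("drug ids must be unique and non-empty")
  }
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    abort("association scores must lie in [0, 1] with no missing values")
  }
  if (!isSymmetric(unclass(m), check.attributes = FALSE)) {
    abort("association matrix must be symmetric")
  }
  structure(m, class = c("assoc_matrix", class(m)), type = type)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "<assoc_matrix> type '%s', %d drugs\n", attr(x, "type"), nrow(x)
  ))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE],
                    6), ...)
  invisible(x)
}

#' Normalize a STITCH-style edge list into an association matrix
#'
#' Text-mining association scores come as an edge list with integer scores on
#' a 0-1000 scale; each score is divided by 1000 and written to both
#' orientations of the pair. Pairs not present in the edge list score 0.
#'
#' @param edges Data frame with columns `drug1`, `drug2`, `score`
#'   (integers in `[0, 1000]`).
#' @param drugs Character vector giving the drug universe (and matrix order);
#'   defaults to the drugs appearing in `edges`.
#' @param type Association type tag for the result, default `"tm"`.
#' @return An [assoc_matrix()].
#' @export
normalize_edge_scores <- function(edges, drugs = NULL, type = "tm") {
  edges <- as_tibble(edges)
  stopifnot(all(c("drug1", "drug2", "score") %in% names(edges)))
  if (nrow(edges) > 0 &&
      (any(edges$score < 0) || any(edges$score > 1000))) {
    abort("edge scores must be integers in [0, 1000]")
  }
  if (is.null(drugs)) drugs <- sort(unique(c(edges$drug1, edges$drug2)))
  m <- matrix(0, length(drugs), length(drugs), dimnames = list(drugs, drugs))
  if (nrow(edges) > 0) {
    i <- match(edges$drug1, drugs)
    j <- match(edges$drug2, drugs)
    if (anyNA(i) || anyNA(j)) abort("edge list names a drug outside `drugs`")
    m[cbind(i, j)] <- edges$score / 1000
    m[cbind(j, i)] <- edges$score / 1000
  }
  diag(m) <- pmax(diag(m), 0)
  assoc_matrix(m, type)
}

#' Read a STITCH-style detailed links file and extract one score column
#'
#' Parses the `chemical_chemical.links.detailed` dialect: columns `chemical1`,
#' `chemical2`, plus one integer column per evidence channel. The requested
#' channel (default `"textmining"`) is selected by header name and normalized
#' with [normalize_edge_scores()].
#'
#' @param path TSV file path.
#' @param channel Score column to extract.
#' @inheritParams normalize_edge_scores
#' @return An [assoc_matrix()].
#' @export
read_stitch_links <- function(path, channel = "textmining", drugs = NULL,
                              type = "tm") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chemical1", "chemical2", channel)
  if (!all(need %in% names(tab))) {
    abort(paste0("links file lacks column(s): ",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  edges <- tibble(
    drug1 = tab$chemical1, drug2 = tab$chemical2,
    score = tab[[channel]]
  )
  normalize_edge_scores(edges, drugs = drugs, type = type)
}

#' Read and write association matrices as TSV
#'
#' The on-disk format has drug ids as the first row and first column and a
#' numeric score in each cell. Writing then re-loading reproduces the scores
#' to full double precision. Asymmetric input is an error unless
#' `symmetrize = TRUE`, which averages the two orientations.
#'
#' @param path TSV file path.
#' @param type Association type tag of the matrix.
#' @param symmetrize Replace scores by the mean of the two orientations
#'   instead of erroring on asymmetric input.
#' @return An [assoc_matrix()].
#' @export
read_assoc_matrix <- function(path, type, symmetrize = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(), drug = readr::col_character()
  ))
  if (names(tab)[1] != "drug") abort("first column must be named 'drug'")
  ids <- tab$drug
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    abort("row and column drug ids of the matrix file do not match")
  }
  if (anyNA(m)) abort("association matrix file contains a non-numeric cell")
  if (any(m < 0) || any(m > 1)) {
    abort("association matrix file contains a value outside [0, 1]")
  }
  if (!isSymmetric(m, check.attributes = FALSE)) {
    if (!symmetrize) {
      abort("matrix file is asymmetric; pass symmetrize = TRUE to average")
    }
    m <- (m + t(m)) / 2
  }
  assoc_matrix(m, type)
}

#' @rdname read_assoc_matrix
#' @param matrix An [assoc_matrix()] to write.
#' @export
write_assoc_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  tab <- as_tibble(unclass(matrix), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble(drug = rownames(matrix)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read per-drug profile files (fingerprints, targets, ATC codes)
#'
#' One line per drug: `drug_id<TAB>comma-separated identifiers`. For
#' fingerprints the identifiers are set-bit indices and are returned as
#' integers; otherwise as character vectors. A drug with an empty second field
#' gets an empty profile.
#'
#' @param path TSV file path.
#' @param integer_bits Convert identifiers to integers (fingerprint bitsets).
#' @return Named list of profile vectors, one per drug.
#' @export
read_profiles <- function(path, integer_bits = FALSE) {
  tab <- readr::read_tsv(
    path,
    col_names = c("drug", "items"),
    col_types = readr::cols(
      drug = readr::col_character(), items = readr::col_character()
    )
  )
  out <- lapply(tab$items, function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  if (integer_bits) out <- lapply(out, as.integer)
  setNames(out, tab$drug)
}
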