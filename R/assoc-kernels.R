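#' Tanimoto coefficient between two fingerprint bitsets
#'
#' Chemical-fingerprint association between two drugs, computed on the sets of
#' set-bit indices of their fingerprints (e.g. ECFP_4): the size of the
#' intersection over the size of the union.
#'
#' @param fp1,fp2 Integer (or character) vectors of set-bit indices. Duplicates
#'   are ignored.
#' @return A similarity score in `[0, 1]`. Two empty fingerprints score 0 by
#'   convention.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(fp1, fp2) {
  fp1 <- unique(fp1)
  fp2 <- unique(fp2)
  u <- length(fp1) + length(fp2) - sum(fp1 %in% fp2)
  if (u == 0) return(0)
  sum(fp1 %in% fp2) / u
}

#' Cosine similarity between two target-protein profiles
#'
#' Drugs are one-hot encoded over their target proteins; the association is
#' the direction cosine of the two binary vectors, i.e.
#' `|T1 n T2| / (sqrt(|T1|) * sqrt(|T2|))`.
#'
#' @param t1,t2 Character vectors of target-protein identifiers.
#' @return A similarity score in `[0, 1]`; 0 if either profile is empty.
#' @examples
#' target_cosine(c("P1", "P2"), c("P2", "P3")) # 0.5
#' @export
target_cosine <- function(t1, t2) {
  t1 <- unique(t1)
  t2 <- unique(t2)
  if (length(t1) == 0 || length(t2) == 0) return(0)
  sum(t1 %in% t2) / (sqrt(length(t1)) * sqrt(length(t2)))
}

#' Hierarchical similarity between two sets of ATC codes
#'
#' Each drug carries a set of 7-character five-level ATC codes
#' (letter, 2 digits, 2 letters, 2 digits; e.g. `"A01AB06"`). For each of the
#' five hierarchy levels the Jaccard index of the level-prefix sets is taken,
#' and the five indices are averaged. The score is monotone in shared
#' hierarchy depth, symmetric, and bounded in `[0, 1]`.
#'
#' @param a1,a2 Character vectors of five-level ATC codes.
#' @return A similarity score in `[0, 1]`; 0 if either set is empty.
#' @examples
#' atc_similarity("A01AB06", "A01AC05") # 0.6: levels 1-3 shared, 4-5 not
#' @export
atc_similarity <- function(a1, a2) {
  a1 <- unique(a1)
  a2 <- unique(a2)
  if (length(a1) == 0 || length(a2) == 0) return(0)
  bad <- c(a1, a2)[!grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", c(a1, a2))]
  if (length(bad) > 0) {
    abort(paste0("not a 7-character five-level ATC code: ", bad[1]))
  }
  lens <- c(1L, 3L, 4L, 5L, 7L) # prefix length of ATC levels 1..5
  mean(vapply(lens, function(l) {
    p1 <- unique(substr(a1, 1L, l))
    p2 <- unique(substr(a2, 1L, l))
    sum(p1 %in% p2) / (length(p1) + length(p2) - sum(p1 %in% p2))
  }, numeric(1)))
}

#' Build an association matrix by applying a kernel to per-drug profiles
#'
#' Computes all pairwise scores for a named list of profiles (fingerprint
#' bitsets, target sets, or ATC code sets) and assembles them into a symmetric
#' [assoc_matrix()].
#'
#' @param profiles Named list: one profile vector per drug.
#' @param type Association type tag, one of `"f"`, `"s"`, `"a"`, `"tm"`, `"t"`.
#' @param kernel Similarity function of two profiles; defaults by type
#'   (`"f"` -> [tanimoto()], `"t"` -> [target_cosine()], `"a"` ->
#'   [atc_similarity()]).
#' @return An [assoc_matrix()] over the drugs in `profiles`.
#' @export
assoc_from_profiles <- function(profiles, type, kernel = NULL) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  if (is.null(kernel)) {
    kernel <- switch(type,
      f = tanimoto,
      t = target_cosine,
      a = atc_similarity,
      abort(paste0("no default kernel for type '", type, "'; pass one"))
    )
  }
  ids <- names(profiles)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- kernel(profiles[[i]], profiles[[j]])
    }
  }
  assoc_matrix(m, type)
}
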