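# Hypergeometric overrepresentation analysis over GMT gene-set collections.
#
# The statistic is the classical upper-tail hypergeometric: with N
# background genes of which K belong to the set, and a query of n genes of
# which k fall in the set, p = P(X >= k). The tail is accumulated in
# log-space from log binomial coefficients, so tiny p-values stay accurate;
# an exhaustive-enumeration oracle backs it in the tests.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (population `N`, `K`
#' successes, `n` draws), computed by log-space summation of the point
#' masses `exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))`.
#'
#' @param k observed overlap count, `0 <= k <= min(K, n)`.
#' @param K number of successes in the population (set size).
#' @param n number of draws (query size).
#' @param N population size (background).
#' @return the tail probability.
#' @export
#' @examples
#' hypergeom_tail(3, 5, 4, 10)  # 55/210
hypergeom_tail <- function(k, K, n, N) {
  for (nm in c("k", "K", "n", "N")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm, min = 0)
    if (v != floor(v)) abort_validation(sprintf("'%s' must be an integer", nm))
  }
  if (K > N || n > N) abort_validation("require K <= N and n <= N")
  if (k > min(K, n)) abort_validation("require k <= min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lo <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lo)
  min(1, exp(m) * sum(exp(lo - m)))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids); names unique,
#'   sets non-empty.
#' @param descriptions optional named character vector of descriptions.
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort_validation("every gene set must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    abort_validation(paste0("duplicate gene-set name(s): ",
                            paste(dup, collapse = ", ")))
  if (any(lengths(sets) == 0))
    abort_validation("gene sets must be non-empty")
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = lapply(sets, as.character),
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Overrepresentation analysis
#'
#' Tests each gene set for enrichment of the query within the background.
#' Identifiers are case-normalised first; sets are intersected with the
#' background before testing, and the reported set size (`go_size`) is the
#' post-intersection size, standard ORA practice. `%Affected` is
#' `100 * count_de / go_size` at one decimal (half away from zero).
#' BH adjustment runs across all tested sets of the collection; rows are
#' sorted by adjusted then raw p-value.
#'
#' @param query_genes character vector of query (e.g. DE) gene ids; must be
#'   a subset of the background.
#' @param collection a [gene_set_collection()].
#' @param background character vector defining the gene universe.
#' @return a `data.frame` of class `enrichment_result` with columns
#'   `set_name`, `count_de`, `go_size`, `pct_affected`, `pvalue`, `qvalue`.
#' @export
ora <- function(query_genes, collection, background) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(normalize_gene_id(background))
  if (length(background) == 0) abort_validation("empty background universe")
  query <- unique(normalize_gene_id(query_genes))
  outside <- setdiff(query, background)
  if (length(outside))
    abort_validation(paste0("query gene(s) outside the background: ",
                            paste(utils::head(outside, 5), collapse = ", ")))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(unique(normalize_gene_id(collection$sets[[nm]])), background)
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(
      set_name = nm, count_de = k, go_size = K,
      pct_affected = if (K == 0) 0 else round_half_away(100 * k / K, 1),
      pvalue = if (K == 0) 1 else hypergeom_tail(k, K, n, N),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- bh_adjust(out$pvalue)
  out <- out[order(out$qvalue, out$pvalue, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("enrichment_result", class(out)))
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate set names and sets without members are rejected with the
#' offending set named.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    abort_parse(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  names_ <- vapply(fields, `[[`, character(1), 1)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup))
    abort_parse(paste0("duplicate gene-set name(s) in GMT: ",
                       paste(dup, collapse = ", ")))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  desc <- setNames(vapply(fields, `[[`, character(1), 2), names_)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
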