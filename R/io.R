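# Tab-separated readers/writers for DE tables, interaction tables and
# pathway topologies. Files may start with '#'-prefixed provenance lines;
# validation failures name the physical line in the file.

read_tsv_body <- function(path, required) {
  lines <- readLines(path, warn = FALSE)
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#"))
    n_comment <- n_comment + 1L
  body <- if (n_comment > 0L) lines[-seq_len(n_comment)] else lines
  if (length(body) == 0L) abort_parse(sprintf("'%s' has no header line", path))
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    abort_parse(sprintf("'%s' line %d: duplicate header column", path, n_comment + 1L))
  miss <- setdiff(required, header)
  if (length(miss))
    abort_parse(sprintf("'%s' line %d: missing column(s) %s", path,
                        n_comment + 1L, paste(miss, collapse = ", ")))
  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  attr(tab, "first_data_line") <- n_comment + 2L
  tab
}

num_col <- function(tab, col, path) {
  v <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- which(is.na(v) & !(tab[[col]] %in% c("NA", "NaN", "")))
  if (length(bad))
    abort_parse(sprintf("'%s' line %d: non-numeric value '%s' in column '%s'",
                        path, attr(tab, "first_data_line") + bad[1] - 1L,
                        tab[[col]][bad[1]], col))
  v
}

#' Read a differential-expression table from TSV
#'
#' Required columns: `feature_id`, `feature_class`, `log2fc`, `pvalue`;
#' `qvalue` is recomputed with [bh_adjust()] when absent. Leading `#`
#' provenance lines are skipped; malformed values are reported with their
#' line number.
#'
#' @param path file path.
#' @return a [de_table()].
#' @export
read_de_table <- function(path) {
  tab <- read_tsv_body(path, c("feature_id", "feature_class", "log2fc", "pvalue"))
  bad <- which(!(tab$feature_class %in% c("gene", "miRNA", "lncRNA")))
  if (length(bad))
    abort_parse(sprintf("'%s' line %d: unknown feature_class '%s'", path,
                        attr(tab, "first_data_line") + bad[1] - 1L,
                        tab$feature_class[bad[1]]))
  de_table(tab$feature_id, tab$feature_class,
           num_col(tab, "log2fc", path), num_col(tab, "pvalue", path),
           qvalue = if ("qvalue" %in% names(tab)) num_col(tab, "qvalue", path))
}

#' Write a differential-expression table as TSV
#'
#' @param table a [de_table()].
#' @param path output file path.
#' @param provenance optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path, provenance = NULL) {
  write_tsv_with_header(
    table[intersect(c("feature_id", "feature_class", "log2fc", "pvalue", "qvalue"),
                    names(table))],
    path, provenance)
}

#' Read a regulator-target interaction table from TSV
#'
#' Required columns: `regulator_id`, `regulator_class`, `target_gene`;
#' optional `source_db`, `evidence`. An unknown regulator class is an error
#' naming the offending line.
#'
#' @param path file path.
#' @return a validated interaction `data.frame`.
#' @export
read_edge_table <- function(path) {
  tab <- read_tsv_body(path, c("regulator_id", "regulator_class", "target_gene"))
  bad <- which(!(tab$regulator_class %in% c("miRNA", "lncRNA")))
  if (length(bad))
    abort_parse(sprintf("'%s' line %d: unknown regulator_class '%s'", path,
                        attr(tab, "first_data_line") + bad[1] - 1L,
                        tab$regulator_class[bad[1]]))
  attr(tab, "first_data_line") <- NULL
  validate_interactions(tab)
}

#' Write an interaction table as TSV
#'
#' @param interactions interaction `data.frame`.
#' @param path output file path.
#' @param provenance optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(interactions, path, provenance = NULL) {
  write_tsv_with_header(interactions, path, provenance)
}

#' Read a signed pathway topology from TSV
#'
#' Four columns: `source`, `target`, `weight` (+1/-1), `relation`.
#'
#' @param path file path.
#' @return a [pathway_topology()].
#' @export
read_pathway <- function(path) {
  tab <- read_tsv_body(path, c("source", "target", "weight"))
  w <- num_col(tab, "weight", path)
  bad <- which(!(w %in% c(-1, 1)))
  if (length(bad))
    abort_parse(sprintf("'%s' line %d: weight must be +1 or -1, got '%s'", path,
                        attr(tab, "first_data_line") + bad[1] - 1L,
                        tab$weight[bad[1]]))
  edges <- data.frame(source = tab$source, target = tab$target, weight = w,
                      relation = tab$relation %||%
                        ifelse(w > 0, "activation", "inhibition"),
                      stringsAsFactors = FALSE)
  pathway_topology(unique(c(edges$source, edges$target)), edges)
}

#' Write a pathway topology as TSV
#'
#' @param topology a [pathway_topology()].
#' @param path output file path.
#' @param provenance optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(topology, path, provenance = NULL) {
  write_tsv_with_header(topology$edges[c("source", "target", "weight", "relation")],
                        path, provenance)
}

write_tsv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(provenance, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
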