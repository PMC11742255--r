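# OTU-table handling: construction, rarefaction, alpha diversity and
# prevalence filtering ahead of network inference. Tables hold taxa as rows
# and samples as columns, the layout amplicon pipelines exchange as TSV/BIOM.

#' Construct an OTU table
#'
#' @param counts non-negative integer matrix, taxa x samples. Row and column
#'   names are used as taxon and sample ids unless overridden.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param taxon_ids,sample_ids optional id vectors.
#' @return An object of class `otu_table`: the counts matrix with a `domain`
#'   attribute.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("OTU", 1:3), paste0("s", 1:4)))
#' otu_table(m, "bacteria")
#' @export
otu_table <- function(counts, domain = c("bacteria", "fungi"),
                      taxon_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  domain <- match.arg(domain)
  counts <- as.matrix(counts)
  if (is.null(taxon_ids))
    taxon_ids <- sprintf("taxon_%d", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample_%d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(counts) <- list(taxon_ids, sample_ids)
  structure(counts, domain = domain, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table (%s): %d taxa x %d samples, total count %s\n",
              attr(x, "domain"), nrow(x), ncol(x),
              format(sum(x), big.mark = " ")))
  invisible(x)
}

# Rebuild the class/domain attributes after a matrix operation.
as_otu <- function(counts, template) {
  otu_table(counts, domain = attr(template, "domain"))
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples every sample (column) without replacement to exactly `depth`
#' reads, the standard normalisation before alpha-diversity comparison.
#' Deterministic at a fixed seed.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample; must not exceed any column sum.
#' @param seed integer seed.
#' @return A rarefied `otu_table` with every column summing to `depth`.
#' @examples
#' tb <- otu_table(matrix(c(5L, 5L, 8L, 2L), 2, 2,
#'                 dimnames = list(c("a", "b"), c("s1", "s2"))), "fungi")
#' colSums(rarefy(tb, 6, seed = 1))
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  cs <- colSums(table)
  short <- cs < depth
  if (any(short))
    stop("rarefaction depth ", depth, " exceeds column sums of: ",
         paste(colnames(table)[short], collapse = ", "))
  # vegan::rrarefy subsamples without replacement; it works on samples-as-rows
  # (its advisory warning about large minimum counts is redundant here: depth
  # and integrality are validated above)
  res <- with_seed(seed,
                   suppressWarnings(vegan::rrarefy(t(unclass(table)), depth)))
  as_otu(t(res), table)
}

#' Species richness of one sample
#'
#' @param column count vector for one sample.
#' @return Number of taxa with nonzero count.
#' @examples
#' richness(c(3, 0, 1, 7))  # 3
#' @export
richness <- function(column) {
  if (sum(column) <= 0) stop("all-zero sample")
  sum(column > 0)
}

#' Shannon diversity of one sample (natural log)
#'
#' @param column count vector for one sample.
#' @return Shannon index in nats, `-sum(p * log(p))` over nonzero taxa.
#' @examples
#' shannon(rep(1, 10))  # log(10)
#' @export
shannon <- function(column) {
  if (sum(column) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(column, index = "shannon", base = exp(1)))
}

#' Alpha-diversity table
#'
#' Richness and Shannon index for every sample of a (typically rarefied)
#' OTU table.
#'
#' @param table an [otu_table()].
#' @return data.frame with `sample_id`, `richness`, `shannon`, `domain`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = colnames(table),
             richness = apply(table, 2, richness),
             shannon = apply(table, 2, shannon),
             domain = attr(table, "domain"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa present (count > 0) in at least `min_prevalence_fraction` of
#' samples; the boundary is inclusive, so a taxon at exactly the threshold is
#' retained. Rare taxa are removed before co-occurrence inference because
#' correlations among mostly-absent taxa are dominated by zero handling.
#'
#' @param table an [otu_table()].
#' @param min_prevalence_fraction required presence fraction in (0, 1]
#'   (0.8 for bacteria and 0.5 for fungi in the standard workflow).
#' @return Filtered `otu_table`; empty (0-taxon) table with a warning when no
#'   taxon qualifies.
#' @examples
#' tb <- otu_table(matrix(c(1L, 0L, 1L, 1L), 2, 2,
#'                 dimnames = list(c("a", "b"), c("s1", "s2"))), "bacteria")
#' prevalence_filter(tb, 1)   # keeps only taxon b
#' @export
prevalence_filter <- function(table, min_prevalence_fraction) {
  if (min_prevalence_fraction <= 0 || min_prevalence_fraction > 1)
    stop("min_prevalence_fraction must be in (0, 1]")
  prev <- rowMeans(unclass(table) > 0)
  keep <- prev >= min_prevalence_fraction
  if (!any(keep)) {
    warning("prevalence filter removed every taxon")
    return(as_otu(unclass(table)[keep, , drop = FALSE], table))
  }
  as_otu(unclass(table)[keep, , drop = FALSE], table)
}

#' Read / write OTU tables
#'
#' TSV layout: first column `taxon_id`, remaining columns one per sample.
#' BIOM I/O (JSON, format 1.0) goes through the biomformat package.
#'
#' @param path file path.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param table an [otu_table()].
#' @return `read_otu_tsv`/`read_otu_biom` return an `otu_table`;
#'   the writers return `path` invisibly.
#' @export
read_otu_tsv <- function(path, domain = c("bacteria", "fungi")) {
  df <- read_tsv(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  otu_table(counts, match.arg(domain))
}

#' @rdname read_otu_tsv
#' @export
write_otu_tsv <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname read_otu_tsv
#' @export
read_otu_biom <- function(path, domain = c("bacteria", "fungi")) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("biomformat is required for BIOM I/O")
  b <- biomformat::read_biom(path)
  counts <- as(biomformat::biom_data(b), "matrix")
  storage.mode(counts) <- "integer"
  otu_table(counts, match.arg(domain))
}

#' @rdname read_otu_tsv
#' @export
write_otu_biom <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("biomformat is required for BIOM I/O")
  b <- biomformat::make_biom(unclass(table))
  biomformat::write_biom(b, path)
  invisible(path)
}
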