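#' Write the variant universe as a VCF 4.2 file
#'
#' Fixed schema: `CHROM POS ID REF ALT QUAL FILTER INFO` with INFO keys
#' `GENE`, `FUNC` and `AF`. Paired with [read_variants_vcf()].
#'
#' @param pop a `population_model` (or any data.frame with the same columns).
#' @param path output file.
#' @export
write_variants_vcf <- function(pop, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population alt allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(pop)) sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s;FUNC=%s;AF=%.8g",
                                 pop$chrom, as.integer(pop$pos), pop$id, pop$ref,
                                 pop$alt, pop$gene, pop$func, pop$af)
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant-universe VCF written by [write_variants_vcf()]
#' @param path VCF file.
#' @return a `population_model` data.frame.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    pop <- simulate_population(0)
    return(pop)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  info <- vapply(f, `[[`, character(1), 8L)
  pop <- data.frame(
    id = vapply(f, `[[`, character(1), 3L),
    chrom = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)),
    ref = vapply(f, `[[`, character(1), 4L),
    alt = vapply(f, `[[`, character(1), 5L),
    gene = vapply(info, info_get, character(1), "GENE", USE.NAMES = FALSE),
    func = vapply(info, info_get, character(1), "FUNC", USE.NAMES = FALSE),
    af = as.numeric(vapply(info, info_get, character(1), "AF",
                           USE.NAMES = FALSE)),
    stringsAsFactors = FALSE)
  class(pop) <- c("population_model", "data.frame")
  pop
}

#' Write pooled read counts as long-format TSV
#'
#' Columns `variant_id, pool_id, ref_reads, alt_reads`; paired with
#' [read_pool_counts()].
#' @param reads a `pooled_reads` object.
#' @param path output file.
#' @export
write_pool_counts <- function(reads, path) {
  long <- data.frame(
    variant_id = rep(rownames(reads$ref), times = ncol(reads$ref)),
    pool_id = rep(colnames(reads$ref), each = nrow(reads$ref)),
    ref_reads = as.vector(reads$ref),
    alt_reads = as.vector(reads$alt),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled counts written by [write_pool_counts()]
#' @param path TSV file.
#' @return a `pooled_reads` object (without an assignment).
#' @export
read_pool_counts <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  vids <- unique(long$variant_id); pools <- unique(long$pool_id)
  shape <- function(col) {
    m <- matrix(0L, length(vids), length(pools),
                dimnames = list(vids, pools))
    m[cbind(match(long$variant_id, vids), match(long$pool_id, pools))] <-
      as.integer(long[[col]])
    m
  }
  structure(list(ref = shape("ref_reads"), alt = shape("alt_reads"),
                 assignment = NULL),
            class = "pooled_reads")
}

#' Write a genotype matrix as TSV (`NA` missing code)
#' @param genotypes samples x variants matrix with dimnames.
#' @param path output file.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes()]
#' @param path TSV file.
#' @return integer matrix with sample/variant dimnames.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' Write a reference panel as TSV
#'
#' Genotype-count panels get columns `variant_id, chrom, ref, alt, n00, n01,
#' n11, af`; frequency-only panels `variant_id, af`.
#' @param panel a `cohort_panel`, or a data.frame of frequencies.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  df <- if (inherits(panel, "cohort_panel")) panel$counts else panel
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel TSV written by [write_panel()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_panel <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
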