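# Readers and writers for the interchange formats: TSV tables with schema
# validation, GMT gene sets, an optional VCF mutation reader, and round-trip
# serialization of a cohort bundle to a directory of plain-text files.
# All genomic coordinates are 1-based inclusive.

table_schemas <- function() {
  list(
    mutation = list(
      required = c("patient", "chrom", "pos", "gene", "alt_reads",
                   "total_reads", "cn_normal", "cn_tumour", "purity"),
      check = function(d) {
        bad <- which(d$alt_reads > d$total_reads)
        if (length(bad)) {
          stop("mutation table: alt_reads > total_reads at row ", bad[1])
        }
        if (any(d$purity <= 0 | d$purity > 1, na.rm = TRUE)) {
          stop("mutation table: purity outside (0, 1]")
        }
      }),
    segments = list(
      required = c("patient", "chrom", "start", "end", "major_cn",
                   "minor_cn"),
      check = function(d) {
        bad <- which(d$start > d$end)
        if (length(bad)) stop("segment table: start > end at row ", bad[1])
      }),
    clinical = list(required = c("patient"), check = function(d) NULL),
    cells = list(
      required = c("slide_id", "x", "y", "class"),
      check = function(d) {
        if (any(!is.finite(d$x)) || any(!is.finite(d$y))) {
          stop("cell table: non-finite coordinates")
        }
      }),
    hla = list(required = c("patient", "allele", "cn", "p_value"),
               check = function(d) {
                 if (any(d$cn < 0, na.rm = TRUE)) {
                   stop("HLA table: negative copy number")
                 }
               }),
    affinities = list(
      required = c("patient", "peptide_length", "mut_nM", "wt_nM", "tpm"),
      check = function(d) {
        bad <- which(!d$peptide_length %in% 8:11)
        if (length(bad)) {
          stop("affinity table: peptide length outside 8-11 at row ", bad[1])
        }
      }),
    tide = list(required = c("patient", "dysfunction", "exclusion"),
                check = function(d) NULL),
    genome = list(required = c("chrom", "length", "centromere_start",
                               "centromere_end"),
                  check = function(d) {
                    if (any(d$length <= 0)) stop("genome model: length <= 0")
                  })
  )
}

#' Read and schema-validate an interchange table
#'
#' @param path TSV (or CSV for cell tables) file path; gzipped files are
#'   read transparently.
#' @param schema One of "mutation", "segments", "clinical", "cells", "hla",
#'   "affinities", "tide", "genome".
#' @return Validated data.frame.
#' @export
read_tables <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema '", schema, "'")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  sc <- schemas[[schema]]
  miss <- setdiff(sc$required, names(d))
  if (length(miss)) {
    stop(sprintf("%s (%s): missing column(s) %s", path, schema,
                 paste(miss, collapse = ", ")))
  }
  sc$check(d)
  d
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a mutation table from a (minimal) VCF
#'
#' Maps one-sample VCF records to the mutation-table schema: INFO keys
#' `GENE`, `CNN` (germline CN), `CNT` (tumour CN), `PURITY`, optional `CTX`
#' (96-class context), and the sample FORMAT fields `AD` (ref,alt depths).
#' The patient id is the sample column name.
#'
#' @param path Uncompressed VCF path.
#' @return data.frame in the mutation schema.
#' @export
read_mutations_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: no #CHROM header in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  if (length(cols) < 10) stop("VCF must contain one sample column")
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  info <- f[, 8]
  fmt_keys <- strsplit(f[, 9], ":")
  sample_vals <- strsplit(f[, 10], ":")
  ad <- vapply(seq_along(fmt_keys), function(i) {
    sample_vals[[i]][match("AD", fmt_keys[[i]])]
  }, "")
  ad_parts <- strsplit(ad, ",")
  ref_d <- as.integer(vapply(ad_parts, `[`, "", 1))
  alt_d <- as.integer(vapply(ad_parts, `[`, "", 2))
  data.frame(
    patient = cols[10], chrom = f[, 1], pos = as.integer(f[, 2]),
    ref = f[, 4], alt = f[, 5],
    gene = info_get(info, "GENE"),
    alt_reads = alt_d, total_reads = ref_d + alt_d,
    cn_normal = as.integer(info_get(info, "CNN")),
    cn_tumour = as.integer(info_get(info, "CNT")),
    purity = as.numeric(info_get(info, "PURITY")),
    context96 = info_get(info, "CTX"),
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits the same TSV/CSV/GMT formats the featurize readers consume:
#' clinical, mutations, segments, expression counts and gene lengths, gene
#' sets, cell tables (long CSV with slide_id), HLA alleles, affinities,
#' dysfunction/exclusion scores, genome model and the reference signature
#' matrix.
#'
#' @param cohort A `neo_cohort`.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(cohort$clinical, p("clinical.tsv"))
  write_tsv(cohort$mutations, p("mutations.tsv"))
  write_tsv(cohort$segments, p("segments.tsv"))
  cm <- data.frame(gene = rownames(cohort$expression$counts),
                   cohort$expression$counts, check.names = FALSE)
  write_tsv(cm, p("expression_counts.tsv"))
  write_tsv(data.frame(gene = names(cohort$expression$lengths),
                       length = as.integer(cohort$expression$lengths)),
            p("gene_lengths.tsv"))
  write_gmt(c(cohort$expression$gene_sets, cohort$expression$immuno_groups),
            p("gene_sets.gmt"))
  cells <- do.call(rbind, lapply(names(cohort$cells), function(id) {
    cbind(slide_id = id, cohort$cells[[id]])
  }))
  utils::write.table(cells, p("cells.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_tsv(cohort$hla_alleles, p("hla_alleles.tsv"))
  write_tsv(cohort$affinities, p("affinities.tsv"))
  write_tsv(cohort$tide, p("tide.tsv"))
  write_tsv(cohort$config$genome_model, p("genome_model.tsv"))
  ref <- cohort$config$signature_reference
  write_tsv(data.frame(context = rownames(ref), ref, check.names = FALSE),
            p("signature_reference.tsv"))
  write_tsv(cohort$outcomes, p("outcomes.tsv"))
  invisible(dir)
}

#' Read a cohort bundle back from a directory
#'
#' Inverse of [write_cohort()]; schema-validates every table.
#'
#' @param dir Directory written by [write_cohort()] (or assembled by hand in
#'   the same layout).
#' @return A `neo_cohort`-shaped list usable by [build_feature_matrix()].
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  clinical <- read_tables(p("clinical.tsv"), "clinical")
  cm <- utils::read.delim(p("expression_counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cm[, -1, drop = FALSE])
  rownames(counts) <- cm[[1]]
  lens <- utils::read.delim(p("gene_lengths.tsv"))
  sets <- read_gmt(p("gene_sets.gmt"))
  cells_long <- read_tables(p("cells.csv"), "cells")
  cells <- split(cells_long[, c("x", "y", "class")], cells_long$slide_id)
  ref <- read_signature_matrix(p("signature_reference.tsv"))
  out <- list(
    clinical = clinical,
    mutations = read_tables(p("mutations.tsv"), "mutation"),
    segments = read_tables(p("segments.tsv"), "segments"),
    expression = list(
      counts = counts,
      lengths = stats::setNames(lens$length, lens$gene),
      gene_sets = sets[intersect(c("GGI", "ESCELL", "STAT1", "DANAHER_CD8",
                                   "DANAHER_MAST"), names(sets))],
      immuno_groups = sets[intersect(c("mhc", "immunomodulator", "effector",
                                       "suppressor"), names(sets))]
    ),
    cells = cells,
    affinities = read_tables(p("affinities.tsv"), "affinities"),
    hla_alleles = read_tables(p("hla_alleles.tsv"), "hla"),
    tide = read_tables(p("tide.tsv"), "tide"),
    outcomes = utils::read.delim(p("outcomes.tsv")),
    config = list(genome_model = read_tables(p("genome_model.tsv"),
                                             "genome"),
                  signature_reference = ref)
  )
  class(out) <- "neo_cohort"
  out
}
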