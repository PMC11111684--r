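# Format readers and writers. Conventions: feature intervals are 0-based
# half-open (BED) internally; VCF and summary-statistic positions are
# 1-based. All TSV readers are gzip-transparent through base connections.

#' Read dosages from a minimal VCF
#'
#' Uses the DS FORMAT field when present, otherwise GT allele counts of
#' ALT. Multi-allelic records are skipped and counted. Dosages are
#' reported for the ALT allele (a1 = ALT, a2 = REF), matching the
#' generator's dosage convention.
#'
#' @param path VCF file (plain or gzipped)
#' @return a [geno_matrix()]; skipped multi-allelic count in attribute
#'   `"n_multiallelic"`
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  multi <- grepl(",", fx[, "ALT"])
  has_ds <- any(grepl("DS", v@gt[, 1]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
               sum(a == "1"), numeric(1)))
    }
    ds <- apply(gt, 2L, count_alt)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  }
  keep <- !multi
  map <- data.frame(snp = fx[keep, "ID"], chrom = fx[keep, "CHROM"],
                    pos = as.integer(fx[keep, "POS"]),
                    a1 = fx[keep, "ALT"], a2 = fx[keep, "REF"],
                    stringsAsFactors = FALSE)
  G <- geno_matrix(t(ds[keep, , drop = FALSE]), map)
  attr(G, "n_multiallelic") <- sum(multi)
  G
}

#' Write a minimal GT-only VCF
#'
#' Dosages are rounded to hard genotypes; a1 is written as ALT.
#'
#' @param G a [geno_matrix()]
#' @param path output file
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$dosage)), collapse = "\t")),
             con)
  gt_of <- c("0/0", "0/1", "1/1")
  hard <- round(t(G$dosage))
  for (j in seq_len(nrow(G$map))) {
    g <- hard[j, ]
    gs <- ifelse(is.na(g), "./.", gt_of[g + 1L])
    writeLines(paste(c(G$map$chrom[j], G$map$pos[j], G$map$snp[j],
                       G$map$a2[j], G$map$a1[j], ".", "PASS", ".", "GT", gs),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read/write a dosage TSV (variants in columns, metadata header rows)
#' @param G a [geno_matrix()]
#' @param path file path
#' @export
write_dosage_tsv <- function(G, path) {
  meta <- t(as.matrix(G$map[, c("snp", "chrom", "pos", "a1", "a2")]))
  hdr <- cbind(c("snp", "chrom", "pos", "a1", "a2"), meta)
  body <- cbind(rownames(G$dosage), format(G$dosage, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(hdr, 1L, paste, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- parts[1:5]
  names(hdr) <- vapply(hdr, `[[`, character(1), 1L)
  map <- data.frame(snp = hdr$snp[-1], chrom = hdr$chrom[-1],
                    pos = as.integer(hdr$pos[-1]), a1 = hdr$a1[-1],
                    a2 = hdr$a2[-1], stringsAsFactors = FALSE)
  body <- parts[-(1:5)]
  ids <- vapply(body, `[[`, character(1), 1L)
  dosage <- t(vapply(body, function(p) suppressWarnings(as.numeric(p[-1])),
                     numeric(nrow(map))))
  if (nrow(map) == 1L) dosage <- matrix(dosage, ncol = 1L)
  rownames(dosage) <- ids
  geno_matrix(dosage, map)
}

#' Read a BED-like feature annotation
#'
#' Expects chrom/start/end/name/class/family[/strand]; 0-based half-open
#' intervals; output sorted by chrom then start with `length = end - start`.
#'
#' @param path BED file
#' @return a [feature_annotation()] table
#' @export
read_bed_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "feature_id",
                                        "class", "family", "strand")[1:7],
                          fill = TRUE)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    stop_config("start >= end at line ", bad[1L])
  }
  df <- df[order(df$chrom, df$start), ]
  feature_annotation(df$feature_id, df$chrom, df$start, df$end,
                     class = df$class, family = df$family,
                     strand = ifelse(is.na(df$strand) | df$strand == "",
                                     "+", df$strand))
}

#' @rdname read_bed_annotation
#' @param annotation a [feature_annotation()] table
#' @export
write_bed_annotation <- function(annotation, path) {
  utils::write.table(
    annotation[, c("chrom", "start", "end", "feature_id", "class",
                   "family", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a counts TSV (features x samples)
#' @param counts features x samples matrix
#' @param path file path
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(data.frame(feature_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read/write GWAS summary statistics TSV
#'
#' Columns SNP CHR BP A1 A2 Z N [MAF INFO]; internal names are lower case.
#' @param ss summary-statistic data frame
#' @param path file path
#' @export
write_sumstats_tsv <- function(ss, path) {
  out <- ss
  up <- c(snp = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
          z = "Z", n = "N", maf = "MAF", info = "INFO")
  names(out) <- ifelse(names(out) %in% names(up), up[names(out)], names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  dn <- c(SNP = "snp", CHR = "chrom", BP = "pos", A1 = "a1", A2 = "a2",
          Z = "z", N = "n", MAF = "maf", INFO = "info")
  names(df) <- ifelse(names(df) %in% names(dn), dn[names(df)], names(df))
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  if (!all(c("snp", "a1", "a2", "z") %in% names(df))) {
    stop_config("sumstats need at least SNP/A1/A2/Z columns")
  }
  df
}

#' Read/write simplified alignment TSV
#'
#' Columns fragment_id, feature_id, alignment_score; one row per candidate.
#' @param aln an [alignment_set()]
#' @param path file path
#' @export
write_alignments_tsv <- function(aln, path) {
  utils::write.table(
    data.frame(fragment_id = aln$hits$fragment_id,
               feature_id = aln$hits$feature_id,
               alignment_score = aln$hits$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @param feature_index ordered feature ids; defaults to the features seen
#' @export
read_alignments_tsv <- function(path, feature_index = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  hits <- data.frame(fragment_id = df$fragment_id,
                     feature_id = df$feature_id,
                     score = df$alignment_score, stringsAsFactors = FALSE)
  alignment_set(hits, feature_index %||% unique(hits$feature_id))
}

#' Read candidate alignments from a SAM text file
#'
#' Minimal extraction: QNAME as fragment id, RNAME as feature id, and the
#' AS tag as alignment score; one record per candidate. Header lines and
#' unmapped records (RNAME `*`) are skipped.
#'
#' @param path SAM file
#' @param feature_index ordered feature ids; defaults to the features seen
#' @return an [alignment_set()]
#' @export
read_alignments_sam <- function(path, feature_index = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    if (length(p) < 11 || p[3] == "*") return(NULL)
    as_tag <- grep("^AS:i:", p[-(1:11)], value = TRUE)
    score <- if (length(as_tag) > 0) as.numeric(sub("AS:i:", "", as_tag[1]))
             else as.numeric(p[5])  # fall back to MAPQ
    data.frame(fragment_id = p[1], feature_id = p[3], score = score,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) stop_config("no mapped records in ", path)
  alignment_set(hits, feature_index %||% unique(hits$feature_id))
}

#' Write candidate alignments as SAM
#' @param aln an [alignment_set()]
#' @param path output file
#' @export
write_alignments_sam <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (f in aln$feature_index) {
    writeLines(paste0("@SQ\tSN:", f, "\tLN:10000"), con)
  }
  h <- aln$hits
  writeLines(sprintf("%s\t0\t%s\t1\t255\t50M\t*\t0\t0\t*\t*\tAS:i:%d",
                     h$fragment_id, h$feature_id, as.integer(round(h$score))),
             con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, genes... per tab-separated line)
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write a truth table to JSON
#' @param truth a `truth_table`
#' @param path output JSON
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    feature_id = truth$feature_id, class = truth$class,
    h2_cis = truth$h2_cis, alpha = truth$alpha,
    causal = lapply(truth$causal, function(cz)
      list(snps = cz$snps, effects = cz$effects)),
    modules = as.list(truth$modules))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
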