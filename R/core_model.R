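#' Construct a protein dataset
#'
#' Bundles a sample-by-antibody intensity matrix with its sample metadata.
#' Raw intensities are median fluorescence intensities (MFI) from a bead
#' array readout and must be strictly positive; log and normalized data
#' must be finite (missing cells are allowed on the normalized scale,
#' where upstream QC may have removed measurements).
#'
#' @param intensities numeric matrix, rows = samples, columns = antibodies.
#' @param meta data.frame with columns `sample_id`, `individual_id`,
#'   `visit`, `collection_date`, `plate_id`, `assay_batch`, `replicate_of`
#'   aligned to the rows of `intensities`. `replicate_of` names the
#'   sample a duplicate technical assay repeats, `NA` otherwise.
#' @param scale one of `"raw"`, `"log"`, `"normalized"`.
#' @param target_map named character vector mapping antibody id to the
#'   gene symbol of its protein target (optional).
#' @return an object of class `protein_dataset`.
#' @export
protein_dataset <- function(intensities, meta, scale = "raw", target_map = NULL) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  scale <- match.arg(scale, c("raw", "log", "normalized"))
  meta <- as.data.frame(meta)
  ds <- structure(
    list(intensities = intensities, meta = meta, scale = scale,
         target_map = target_map),
    class = "protein_dataset")
  validate_protein_dataset(ds)
  ds
}

meta_columns <- c("sample_id", "individual_id", "visit", "collection_date",
                  "plate_id", "assay_batch", "replicate_of")

#' Validate a protein dataset
#'
#' Checks the structural invariants: unique sample and antibody ids,
#' metadata aligned to rows, positive raw intensities, finite log-scale
#' values, visits in `1..V`, unique (individual, visit, assay batch)
#' triplets and collection dates non-decreasing in visit within an
#' individual.
#'
#' @param ds a `protein_dataset`.
#' @return `ds`, invisibly; errors describe the offending sample or cell.
#' @export
validate_protein_dataset <- function(ds) {
  x <- ds$intensities
  meta <- ds$meta
  missing_cols <- setdiff(meta_columns, names(meta))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(x) != nrow(meta))
    stop("intensity rows (", nrow(x), ") != metadata rows (", nrow(meta), ")")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("antibody ids missing or duplicated")
  if (!is.null(rownames(x)) && !identical(rownames(x), as.character(meta$sample_id)))
    stop("intensity row names do not match metadata sample_id order")
  bad_visit <- which(!is.finite(meta$visit) | meta$visit < 1 |
                       meta$visit != round(meta$visit))
  if (length(bad_visit))
    stop("visit outside 1..V for sample ", meta$sample_id[bad_visit[1]])
  if (ds$scale == "raw") {
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad)) {
      ij <- arrayInd(bad[1], dim(x))
      stop("non-positive raw MFI at sample ", meta$sample_id[ij[1]],
           ", antibody ", colnames(x)[ij[2]])
    }
  } else {
    if (any(!is.finite(x) & !is.na(x)))
      stop("non-finite values on the ", ds$scale, " scale")
    if (ds$scale == "log" && anyNA(x))
      stop("missing values are not allowed on the log scale")
  }
  key <- paste(meta$individual_id, meta$visit, meta$assay_batch)
  if (anyDuplicated(key))
    stop("duplicated (individual_id, visit, assay_batch): ",
         key[duplicated(key)][1])
  dt <- as.Date(meta$collection_date)
  for (id in unique(meta$individual_id)) {
    sel <- meta$individual_id == id & is.na(meta$replicate_of)
    o <- order(meta$visit[sel])
    if (is.unsorted(dt[sel][o]))
      stop("collection_date decreases with visit for individual ", id)
  }
  invisible(ds)
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat("protein_dataset:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "antibodies;", x$scale, "scale;",
      length(unique(x$meta$individual_id)), "individuals,",
      length(unique(x$meta$visit)), "visits,",
      sum(!is.na(x$meta$replicate_of)), "duplicate assays\n")
  invisible(x)
}

#' Read a protein dataset from intensity and metadata tables
#'
#' The intensity TSV holds `sample_id` in the first column and one column
#' per antibody; the metadata TSV holds the sample annotation columns.
#' Samples present in the metadata but absent from the intensity table are
#' dropped with a warning; intensity rows without metadata are an error.
#' Row order of the intensity table is preserved.
#'
#' @param intensity_path,meta_path TSV file paths.
#' @param scale scale tag of the stored values (default `"raw"`).
#' @return a validated [protein_dataset()].
#' @export
read_protein_dataset <- function(intensity_path, meta_path, scale = "raw") {
  tab <- read.delim(intensity_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("first column of the intensity table must be sample_id")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in intensity table: ",
         tab$sample_id[duplicated(tab$sample_id)][1])
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  meta$collection_date <- as.Date(meta$collection_date)
  meta$replicate_of[meta$replicate_of %in% c("", "NA")] <- NA
  absent <- setdiff(tab$sample_id, meta$sample_id)
  if (length(absent))
    stop("intensity samples missing from metadata: ",
         paste(head(absent, 5), collapse = ", "))
  extra <- setdiff(meta$sample_id, tab$sample_id)
  if (length(extra)) {
    warning(length(extra), " metadata samples absent from intensities dropped: ",
            paste(head(extra, 5), collapse = ", "))
    meta <- meta[meta$sample_id %in% tab$sample_id, , drop = FALSE]
  }
  meta <- meta[match(tab$sample_id, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab$sample_id
  protein_dataset(x, meta, scale = scale)
}

#' Write a protein dataset to intensity and metadata tables
#'
#' Inverse of [read_protein_dataset()]; values are serialized at 10
#' significant digits so a read/write round trip is the identity to that
#' precision.
#'
#' @param ds a `protein_dataset`.
#' @param intensity_path,meta_path output TSV paths.
#' @export
write_protein_dataset <- function(ds, intensity_path, meta_path) {
  tab <- data.frame(sample_id = ds$meta$sample_id,
                    signif(ds$intensities, 10), check.names = FALSE)
  write.table(tab, intensity_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ds$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Construct a genotype matrix
#'
#' Additive dosages (counted minor allele, 0/1/2 or real in \[0,2\] for
#' imputed data) for a set of individuals, with per-SNP annotation and
#' gene windows for cis-annotation. Internal genomic coordinates are
#' 1-based inclusive (the VCF convention).
#'
#' @param dosages numeric matrix, rows = individuals (rownames =
#'   individual ids), columns = SNP ids.
#' @param snp_info data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf` aligned to the columns of `dosages`.
#' @param gene_windows data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_info, gene_windows = NULL) {
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(snp_info))
  if (any(snp_info$maf < 0 | snp_info$maf > 0.5, na.rm = TRUE))
    stop("MAF outside [0, 0.5]; orient dosages to the minor allele")
  if (any(snp_info$pos <= 0))
    stop("non-positive SNP position")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages outside [0, 2]")
  structure(list(dosages = dosages, snp_info = as.data.frame(snp_info),
                 gene_windows = gene_windows),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs;",
      if (is.null(x$gene_windows)) 0 else nrow(x$gene_windows),
      "gene windows\n")
  invisible(x)
}

#' Read gene windows from a BED4 file
#'
#' BED is 0-based half-open; windows are converted to the internal
#' 1-based inclusive convention (`start + 1`, `end` unchanged).
#'
#' @param path BED4 file (chrom, start, end, gene name).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_windows <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("gene windows must be BED4 (chrom start end name)")
  data.frame(gene = bed[[4]], chrom = as.character(bed[[1]]),
             start = bed[[2]] + 1L, end = bed[[3]],
             stringsAsFactors = FALSE)
}

orient_to_minor <- function(dosages, snp_info) {
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  flip <- which(freq > 0.5)
  if (length(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- snp_info$ref[flip]
    snp_info$ref[flip] <- snp_info$alt[flip]
    snp_info$alt[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  snp_info$maf <- freq
  list(dosages = dosages, snp_info = snp_info)
}

#' Read genotypes from a VCF or a dosage table
#'
#' VCF input (4.2, via the `vcfR` package) keeps biallelic records only
#' (multi-allelic records are skipped with a logged count) and converts GT
#' calls to additive dosages; a plain dosage TSV holds `individual_id` in
#' the first column and one column per SNP, with SNP coordinates parsed
#' from ids of the form `chrom:pos:ref:alt` when possible. Dosages are
#' oriented so the counted allele is the minor allele and the MAF is
#' recomputed from the data.
#'
#' @param path VCF (`.vcf`) or dosage TSV path.
#' @param gene_window_path optional BED4 path, see [read_gene_windows()].
#' @param individuals optional individual ids that must intersect the
#'   genotyped ids (error if the intersection is empty).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, gene_window_path = NULL, individuals = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi))
      message("skipping ", sum(multi), " multi-allelic records")
    gt <- vcfR::extract.gt(vcf, element = "GT")[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    count_alt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
    }
    dosages <- t(apply(gt, 1, count_alt))
    dosages <- matrix(as.numeric(dosages), nrow = nrow(gt),
                      dimnames = dimnames(gt))
    dosages <- t(dosages)                      # individuals x SNPs
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    colnames(dosages) <- ids
    snp_info <- data.frame(id = ids, chrom = fix$CHROM,
                           pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT, maf = NA_real_,
                           stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    dosages <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dosages) <- tab[[1]]
    parts <- strsplit(colnames(dosages), ":")
    ok <- lengths(parts) >= 2
    snp_info <- data.frame(
      id = colnames(dosages),
      chrom = ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_),
      pos = ifelse(ok, suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))), 1L),
      ref = ifelse(lengths(parts) >= 4, vapply(parts, `[`, "", 3L), "A"),
      alt = ifelse(lengths(parts) >= 4, vapply(parts, `[`, "", 4L), "B"),
      maf = NA_real_, stringsAsFactors = FALSE)
    snp_info$pos[is.na(snp_info$pos)] <- 1L
  }
  if (!is.null(individuals) &&
      !length(intersect(individuals, rownames(dosages))))
    stop("no genotyped individuals overlap the dataset")
  o <- orient_to_minor(dosages, snp_info)
  gw <- if (!is.null(gene_window_path)) read_gene_windows(gene_window_path)
  genotype_matrix(o$dosages, o$snp_info, gw)
}

#' Write a result report to TSV or JSON
#'
#' Column order is kept as-is (deterministic), floats are serialized at 10
#' significant digits; the JSON variant (chosen by a `.json` extension)
#' carries a `schema_version` field.
#'
#' @param report a data.frame-like result table.
#' @param path output path ending in `.tsv` or `.json`.
#' @export
write_report <- function(report, path) {
  report <- as.data.frame(report)
  num <- vapply(report, is.double, TRUE)
  report[num] <- lapply(report[num], signif, digits = 10)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(schema_version = 1L, rows = report), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a report written by [write_report()]
#' @param path TSV or JSON path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$rows)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Read a clinical trait table
#'
#' Traits are keyed by `(individual_id, visit)`; additional static
#' covariates (sex, age, BMI) may repeat across visits.
#'
#' @param path TSV with columns `individual_id`, `visit` and one column
#'   per trait.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "visit") %in% names(tr)))
    stop("trait table must have individual_id and visit columns")
  tr
}

# Per-(individual, visit) matrix with duplicate assays averaged.
# Returns list(values, info) with info rows aligned to the matrix.
collapse_assays <- function(ds) {
  meta <- ds$meta
  key <- paste(meta$individual_id, meta$visit, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  values <- rowsum(ds$intensities, grp, reorder = FALSE)
  counts <- as.vector(table(factor(grp, levels = seq_len(sum(first)))))
  values <- values / counts
  info <- data.frame(individual_id = meta$individual_id[first],
                     visit = meta$visit[first],
                     collection_date = as.Date(meta$collection_date[first]),
                     stringsAsFactors = FALSE)
  rownames(values) <- paste(info$individual_id, info$visit, sep = "_v")
  list(values = values, info = info)
}
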