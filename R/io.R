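## Plain-text readers and writers for the pipeline's inputs and outputs.
## Waveforms travel as a long-wide TSV (sample_id, modality, v0...),
## genotypes as a dosage matrix plus a variant sidecar table (or a
## minimal VCF with a DS FORMAT field), intervals as BED.

#' Write waveforms to a wide TSV
#'
#' One row per (sample, modality); value columns `v0...` are padded with
#' NA up to the longest modality.
#'
#' @param waves Named list of per-modality matrices (rownames = ids).
#' @param path Output file.
#' @export
write_waveforms_tsv <- function(waves, path) {
  maxl <- max(vapply(waves, ncol, 1L))
  rows <- lapply(names(waves), function(mod) {
    m <- waves[[mod]]
    pad <- matrix(NA_real_, nrow(m), maxl - ncol(m))
    data.frame(sample_id = rownames(m), modality = mod,
               cbind(m, pad), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("sample_id", "modality", paste0("v", seq_len(maxl) - 1))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read waveforms from a wide TSV
#'
#' @param path File written by [write_waveforms_tsv()].
#' @return Named list of per-modality matrices (trailing NA padding
#'   trimmed).
#' @export
read_waveforms_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  out <- lapply(split(seq_len(nrow(tab)), tab$modality), function(idx) {
    m <- vals[idx, , drop = FALSE]
    keep <- colSums(!is.na(m)) > 0
    m <- m[, keep, drop = FALSE]
    rownames(m) <- tab$sample_id[idx]
    colnames(m) <- NULL
    m
  })
  out[unique(tab$modality)]
}

#' Write / read a split manifest (sample_id, split)
#' @param split Named factor/character from [assign_split()].
#' @param path File path.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.table(data.frame(sample_id = names(split),
                                split = as.character(split)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(factor(tab$split, levels = c("train", "val", "test")),
                  tab$sample_id)
}

#' Write / read genotypes as dosage matrix + variant sidecar
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Two files are written: `<prefix>.dosage.tsv` and
#'   `<prefix>.variants.tsv`.
#' @export
write_genotypes <- function(geno, prefix) {
  dos <- data.frame(sample_id = rownames(geno$dosages), geno$dosages,
                    check.names = FALSE)
  utils::write.table(dos, paste0(prefix, ".dosage.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(geno$variants, paste0(prefix, ".variants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(prefix) {
  dos <- utils::read.delim(paste0(prefix, ".dosage.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- dos$sample_id
  dos <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dos) <- ids
  variants <- utils::read.delim(paste0(prefix, ".variants.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character"))
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix")
}

#' Write genotypes as a minimal VCF with a DS FORMAT field
#'
#' @param geno A `genotype_matrix`.
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_vcf_ds <- function(geno, path) {
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(geno$dosages)), collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "DS",
                       formatC(geno$dosages[, j], format = "g")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Uses vcfR when available.
#'
#' @param path VCF path.
#' @return A `genotype_matrix` (QC metadata columns filled with
#'   defaults where the VCF does not carry them).
#' @export
read_vcf_ds <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    mr_stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  dos <- t(ds)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  maf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.numeric(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         maf = maf, info = 1,
                         missing_frac = colMeans(is.na(dos)),
                         hwe_p = 1, stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix")
}

#' Read a BED file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; positions are converted on read so all
#' internal coordinates are 1-based inclusive (VCF convention).
#'
#' @param path BED path (first three columns used).
#' @return data.frame with chrom, start, end.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) mr_stop("BED needs at least 3 columns")
  data.frame(chrom = as.character(tab[[1]]),
             start = tab[[2]] + 1, end = tab[[3]],
             stringsAsFactors = FALSE)
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with chrom, start, end (1-based
#'   inclusive).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(data.frame(intervals$chrom, intervals$start - 1,
                                intervals$end),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' Write embeddings as TSV (sample_id, e1...ed)
#' @param emb An `embedding_matrix`.
#' @param path Output path.
#' @export
write_embeddings_tsv <- function(emb, path) {
  utils::write.table(data.frame(sample_id = emb$sample_ids, emb$values,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write PRS weights as TSV (variant id, chrom, pos, effect allele,
#' weight)
#' @param model A `prs_model`.
#' @param variants Variant table supplying chrom/pos/alt.
#' @param path Output path.
#' @export
write_prs_weights <- function(model, variants, path) {
  v <- variants[match(model$variants, variants$id), ]
  utils::write.table(data.frame(id = model$variants, chrom = v$chrom,
                                pos = v$pos, effect_allele = v$alt,
                                weight = unname(model$weights)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}
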