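#' Write a genotype matrix as a minimal VCF plus population map
#'
#' Emits a GT-only VCF (unphased diploid dosages; missing as `./.`) and a
#' two-column population-map TSV (`individual<TAB>population`). Internal
#' 0-based positions are converted to VCF's 1-based convention at this
#' boundary.
#'
#' @param gm A [genotype_matrix()].
#' @param vcf Path of the VCF to write.
#' @param popmap Optional path of the population-map TSV.
#' @return `vcf`, invisibly.
#' @export
write_genotypes <- function(gm, vcf, popmap = NULL) {
  inds <- colnames(gm$geno)
  gt <- matrix("./.", nrow(gm$geno), length(inds))
  gt[!is.na(gm$geno) & gm$geno == 0L] <- "0/0"
  gt[!is.na(gm$geno) & gm$geno == 1L] <- "0/1"
  gt[!is.na(gm$geno) & gm$geno == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mscdiscord",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", inds), collapse = "\t"))
  body <- paste(gm$variants$chrom, gm$variants$pos + 1L, ".",
                gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf)
  if (!is.null(popmap)) write_popmap(gm$pop, popmap)
  invisible(vcf)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Loads biallelic SNVs from a VCF (through `vcfR` when installed, falling
#' back to a plain-text reader for the GT-only subset this package writes).
#' Multi-allelic records are skipped with a message. VCF 1-based positions
#' are converted to the package's 0-based convention.
#'
#' @param vcf Path to the VCF.
#' @param popmap Path to a two-column TSV (individual, population), or a
#'   named character vector.
#' @param outgroup Outgroup population label (or `NA`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf, popmap, outgroup = NA_character_) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(vcf, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"]) - 1L
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  } else {
    lines <- readLines(vcf)
    hdr <- grep("^#CHROM", lines)
    stop_if_not(length(hdr) == 1, "malformed VCF: no #CHROM header")
    cols <- strsplit(lines[hdr], "\t")[[1]]
    body <- strsplit(lines[-seq_len(hdr)], "\t")
    body <- body[lengths(body) == length(cols)]
    m <- do.call(rbind, body)
    chrom <- m[, 1]; pos <- as.integer(m[, 2]) - 1L
    ref <- m[, 4]; alt <- m[, 5]
    gt_raw <- m[, 10:length(cols), drop = FALSE]
    colnames(gt_raw) <- cols[10:length(cols)]
    gt_raw <- sub(":.*", "", gt_raw)
  }
  multi <- grepl(",", alt) | nchar(ref) > 1 | nchar(alt) > 1
  if (any(multi))
    message(sum(multi), " multi-allelic/non-SNV record(s) skipped")
  keep <- !multi
  dose <- matrix(NA_integer_, sum(keep), ncol(gt_raw),
                 dimnames = list(NULL, colnames(gt_raw)))
  gsub_gt <- gsub("\\|", "/", gt_raw[keep, , drop = FALSE])
  dose[gsub_gt == "0/0"] <- 0L
  dose[gsub_gt %in% c("0/1", "1/0")] <- 1L
  dose[gsub_gt == "1/1"] <- 2L
  pop <- if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap))
    read_popmap(popmap) else popmap
  genotype_matrix(data.frame(chrom = chrom[keep], pos = pos[keep],
                             ref = ref[keep], alt = alt[keep],
                             stringsAsFactors = FALSE),
                  dose, pop, outgroup)
}

#' @rdname read_genotypes
#' @param pop Named character vector individual -> population.
#' @param path File path.
#' @export
write_popmap <- function(pop, path) {
  write.table(data.frame(individual = names(pop), population = unname(pop)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_popmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("individual", "population"),
                   stringsAsFactors = FALSE)
  setNames(df$population, df$individual)
}

#' Read and write gene-tree lists (one Newick per line)
#'
#' Square-bracket comments (e.g. window ids) are tolerated on reading and
#' stripped before parsing; malformed lines raise an error naming the line
#' number.
#'
#' @param path File path.
#' @return `read_trees`: a list of `phylo` objects.
#' @export
read_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    txt <- gsub("\\[[^]]*\\]", "", lines[i])
    tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
    if (is.null(tr)) stop(sprintf("malformed Newick on line %d of %s", i,
                                  path), call. = FALSE)
    trees[[i]] <- tr
  }
  trees
}

#' @rdname read_trees
#' @param trees List of `phylo` trees (filtered windows are skipped).
#' @param comments Optional character vector of per-tree comments, written
#'   as leading `[...]` blocks (e.g. window ids).
#' @export
write_trees <- function(trees, path, comments = NULL) {
  keep <- !vapply(trees, inherits, logical(1), "filtered_window")
  lines <- vapply(trees[keep], ape::write.tree, character(1))
  if (!is.null(comments))
    lines <- paste0("[", comments[keep], "]", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a BED file (0-based half-open) or a TSV with a config stamp
#'
#' @param df `data.frame`; for BED the first three columns must be `chrom`,
#'   `start`, `end`.
#' @param path File path.
#' @param config_hash Optional configuration fingerprint written as a
#'   leading `#` comment line of the TSV.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stop_if_not(all(c("chrom", "start", "end") %in% names(df)),
              "BED needs chrom, start, end")
  write.table(df[, c("chrom", "start", "end"),
                 drop = FALSE],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config=", config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
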