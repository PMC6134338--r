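#' Candidate gene regions (hg19)
#'
#' The two regions analysed by the pipeline: the CNTNAP2 exon 13-14 region on
#' chromosome 7 and the NRXN1 5' region (exons 1-4 plus 20 kb upstream) on
#' chromosome 2. Coordinates are 1-based inclusive hg19 intervals.
#'
#' @return A data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
default_regions <- function() {
  data.frame(
    gene = c("CNTNAP2", "NRXN1"),
    chrom = c("7", "2"),
    start = c(147514390L, 51141501L),
    end = c(147612852L, 51280121L),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic SNP panel
#'
#' A 47-SNP panel emulating the study layout: 24 SNPs in the CNTNAP2 region
#' (22 array SNPs plus the two classical association SNPs rs2710102 and
#' rs7794745) and 23 SNPs in the NRXN1 region. Positions are evenly spaced
#' within each hg19 interval; minor allele frequencies cycle over a fixed set
#' of common values, with SNPs that share an LD block given equal frequencies
#' so that high pairwise r-squared targets are attainable.
#'
#' The accompanying LD target ([default_ld()]) engineers six CNTNAP2 pairs and
#' eight NRXN1 pairs with r-squared above 0.8, mirroring the LD summary the
#' candidate-region analysis reports.
#'
#' @return A data frame of SNP specs: `snp_id`, `chrom`, `pos`, `maf`, `gene`,
#'   `a1`, `a2`, `ld_block`.
#' @export
default_snp_panel <- function() {
  regions <- default_regions()
  make_gene <- function(gene, n, ids = NULL) {
    r <- regions[regions$gene == gene, ]
    pos <- round(seq(r$start, r$end, length.out = n))
    snp_id <- if (is.null(ids)) {
      sprintf("%s_%02d", tolower(gene), seq_len(n))
    } else {
      ids
    }
    data.frame(
      snp_id = snp_id, chrom = r$chrom, pos = pos,
      gene = gene, stringsAsFactors = FALSE
    )
  }
  cnt_ids <- sprintf("cntnap2_%02d", 1:24)
  cnt_ids[11] <- "rs2710102"
  cnt_ids[17] <- "rs7794745"
  panel <- rbind(
    make_gene("CNTNAP2", 24, cnt_ids),
    make_gene("NRXN1", 23)
  )

  # block 0 = independent; blocks > 0 share a latent LD cluster
  panel$ld_block <- 0L
  panel$ld_block[1:4] <- 1L          # CNTNAP2: C(4,2) = 6 pairs > 0.8
  panel$ld_block[25:28] <- 2L        # NRXN1: 6 pairs ...
  panel$ld_block[30:31] <- 3L        # ... + 1 pair
  panel$ld_block[33:34] <- 4L        # ... + 1 pair = 8 pairs > 0.8

  maf_cycle <- c(0.08, 0.15, 0.22, 0.31, 0.38, 0.45, 0.12, 0.27, 0.35, 0.19)
  panel$maf <- maf_cycle[(seq_len(nrow(panel)) - 1L) %% length(maf_cycle) + 1L]
  for (b in setdiff(unique(panel$ld_block), 0L)) {
    idx <- which(panel$ld_block == b)
    panel$maf[idx] <- panel$maf[idx[1]]
  }
  alleles <- c("A", "C", "G", "T")
  panel$a1 <- alleles[(seq_len(nrow(panel)) - 1L) %% 2L + 1L]      # A / C
  panel$a2 <- alleles[(seq_len(nrow(panel)) - 1L) %% 2L + 3L]      # G / T
  panel
}

#' Default LD target matrix for a SNP panel
#'
#' Builds a symmetric target r-squared matrix from the `ld_block` column of a
#' panel: SNPs in the same block get the block's r-squared (0.85 for the
#' 4-SNP clusters, 0.90 for the 2-SNP clusters), everything else 0.
#'
#' @param panel a SNP spec table as from [default_snp_panel()].
#' @param block_r2 r-squared within a block; recycled over blocks.
#' @return A `m x m` matrix with unit diagonal, values in `[0, 1]`.
#' @export
default_ld <- function(panel = default_snp_panel(),
                       block_r2 = c(0.85, 0.85, 0.90, 0.90)) {
  m <- nrow(panel)
  R2 <- diag(m)
  blocks <- setdiff(sort(unique(panel$ld_block)), 0L)
  block_r2 <- rep_len(block_r2, max(length(blocks), 1L))
  for (k in seq_along(blocks)) {
    idx <- which(panel$ld_block == blocks[k])
    R2[idx, idx] <- block_r2[k]
  }
  diag(R2) <- 1
  dimnames(R2) <- list(panel$snp_id, panel$snp_id)
  R2
}
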