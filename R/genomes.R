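# genome descriptions: a genome is a tibble (chrom, length, centromere)

#' Genome descriptions
#'
#' A genome is described by a tibble with one row per chromosome and columns
#' `chrom` (character), `length` (bp) and `centromere` (bp position splitting
#' p and q arms; used only for arm labels and chromothripsis arm spans).
#'
#' `hg19_genome()` returns the GRCh37/hg19 chromosome lengths with approximate
#' centromere midpoints. `toy_genome()` returns a small configurable genome
#' used as the default desk-scale test fixture; per-chromosome lengths of
#' 100-150 Mb keep arm-level lesions and the 10 Mb cnLOH windows realistic
#' while an order of magnitude smaller than hg19.
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @param centromere_frac fraction of the length at which the centromere sits.
#' @return tibble with columns `chrom`, `length`, `centromere`.
#' @export
#' @examples
#' toy_genome()
toy_genome <- function(lengths = c(`1` = 150e6, `2` = 120e6, `3` = 100e6),
                       centromere_frac = 0.4) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  tibble::tibble(
    chrom = names(lengths),
    length = unname(as.numeric(lengths)),
    centromere = unname(as.numeric(lengths)) * centromere_frac
  )
}

#' @rdname toy_genome
#' @param include_sex include chrX/chrY rows.
#' @export
hg19_genome <- function(include_sex = TRUE) {
  g <- tibble::tribble(
    ~chrom, ~length, ~centromere,
    "1", 249250621, 125000000,
    "2", 243199373, 93300000,
    "3", 198022430, 91000000,
    "4", 191154276, 50400000,
    "5", 180915260, 48400000,
    "6", 171115067, 61000000,
    "7", 159138663, 59900000,
    "8", 146364022, 45600000,
    "9", 141213431, 49000000,
    "10", 135534747, 40200000,
    "11", 135006516, 53700000,
    "12", 133851895, 35800000,
    "13", 115169878, 17900000,
    "14", 107349540, 17600000,
    "15", 102531392, 19000000,
    "16", 90354753, 36600000,
    "17", 81195210, 24000000,
    "18", 78077248, 17200000,
    "19", 59128983, 26500000,
    "20", 63025520, 27500000,
    "21", 48129895, 13200000,
    "22", 51304566, 14700000,
    "X", 155270560, 60600000,
    "Y", 59373566, 12500000
  )
  if (!include_sex) g <- dplyr::filter(g, !.data$chrom %in% c("X", "Y"))
  g
}

genome_total_length <- function(genome) sum(genome$length)

#' Default backbone SNP density
#'
#' The shipped panel places 172,470 backbone SNPs across the genome; this is
#' the corresponding density in SNPs per bp, used to scale panels for smaller
#' (toy) genomes so that, e.g., a 10 Mb window still contains several hundred
#' SNPs.
#'
#' @return SNPs per bp (numeric scalar).
#' @export
default_snp_density <- function() {
  172470 / genome_total_length(hg19_genome())
}

arm_of <- function(genome, chrom, pos) {
  cen <- genome$centromere[match(chrom, genome$chrom)]
  ifelse(pos <= cen, "p", "q")
}

chrom_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}
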