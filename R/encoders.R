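#' Inheritance-model genotype encodings
#'
#' The additive coding 0/1/2 counts copies of one allele. The five
#' alternative encoders re-map every genotype in the data to express a
#' different inheritance model:
#'
#' * `dominant`   0,1,2 -> 0,2,2  (heterozygote equals the alternate homozygote)
#' * `recessive`  0,1,2 -> 0,0,2  (heterozygote equals the reference homozygote)
#' * `heterosis`  0,1,2 -> 0,2,0  (the two homozygotes are equal)
#' * `overdominance`  0,1,2 -> 0,2,1  (heterozygote above both homozygotes)
#' * `underdominance` 0,1,2 -> 1,0,2  (heterozygote below both homozygotes)
#'
#' `additive` is the identity and is the default absence of any encoder.
#' Encoders compose: applying several in sequence can reach inheritance
#' models not expressible by any single encoder.
#'
#' @format `encoding_tables` is a named list of integer vectors of length 3,
#'   giving the image of codes 0, 1, 2.
#' @export
encoding_tables <- list(
  additive       = c(0L, 1L, 2L),
  dominant       = c(0L, 2L, 2L),
  recessive      = c(0L, 0L, 2L),
  heterosis      = c(0L, 2L, 0L),
  overdominance  = c(0L, 2L, 1L),
  underdominance = c(1L, 0L, 2L)
)

#' Look up an encoding table by name
#' @param map an encoder name or an integer vector of length 3 over 0..2.
#' @return integer vector of length 3 (images of codes 0, 1, 2).
#' @export
encoding_table <- function(map) {
  if (is.character(map)) {
    if (!map %in% names(encoding_tables)) stop("unknown encoder: ", map)
    return(encoding_tables[[map]])
  }
  tab <- as.integer(map)
  if (length(tab) != 3 || any(!tab %in% 0:2))
    stop("an encoding table must map {0,1,2} into {0,1,2}")
  tab
}

#' Apply an inheritance-model encoding to every genotype
#'
#' @param genotypes samples x loci matrix with codes in the table's domain.
#' @param map encoder name or length-3 table (see [encoding_table()]).
#' @return matrix of the same shape and identifiers, element-wise re-coded.
#' @export
apply_encoding <- function(genotypes, map) {
  tab <- encoding_table(map)
  if (any(!genotypes %in% 0:2))
    stop("genotype codes outside {0,1,2} cannot be encoded")
  out <- genotypes
  out[] <- tab[genotypes + 1L]
  out
}

#' Compose encodings left to right
#'
#' `compose_encodings(c("recessive", "overdominance"))` is the table of
#' "recessive, then overdominance". The six named maps are closed under
#' composition on the domain \{0,1,2\}, so the result is always itself a
#' valid encoding table (possibly one no single encoder produces).
#'
#' @param maps non-empty vector/list of encoder names or tables.
#' @return integer vector of length 3.
#' @export
compose_encodings <- function(maps) {
  if (length(maps) == 0) stop("need at least one encoding to compose")
  Reduce(function(acc, m) encoding_table(m)[acc + 1L],
         maps, encoding_table("additive"))
}

#' Number of distinct genotype values an encoding produces
#'
#' Dominant, recessive and heterosis collapse the three genotype codes to two
#' distinct values ("2-level"); overdominance and underdominance permute them
#' ("3-level"). Used to classify the final inheritance model of a pipeline.
#'
#' @param map encoder name or table.
#' @export
encoding_levels <- function(map) {
  length(unique(encoding_table(map)))
}
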