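# Reference annotation counts of the four-library drought study design the
# package models. These are inputs for the summary arithmetic (percentage
# formatting, common-unique fractions), not results computed here.

#' Annotation counts of the four-library drought study
#'
#' Unique-tag and total-read counts per annotation class for the four sRNA
#' libraries (PA2 and PA4: diploid and autotetraploid controls; PA2H and
#' PA4H: their drought-stressed counterparts), as tabulated for the study
#' design this package models. Used to exercise the annotation summary
#' arithmetic on real library-scale numbers.
#'
#' @return A list with two integer matrices, `unique` and `total`
#'   (rows: Total + annotation classes, columns: libraries), and
#'   `common_unique`, the reference counts of unique tags shared between
#'   each control and its stressed counterpart.
#' @export
study_annotation_counts <- function() {
  libs <- c("PA2", "PA2H", "PA4", "PA4H")
  classes <- c("Total", "miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unann")
  uq <- matrix(c(
    4270792, 3930801, 3691101, 4814893,   # Total
    16088,   19871,   18497,   23522,     # miRNA
    46205,   60699,   72532,   78618,     # rRNA
    1625,    1753,    1765,    2088,      # snRNA
    597,     754,     580,     775,       # snoRNA
    8310,    14598,   16917,   13870,     # tRNA
    4197967, 3833126, 3580810, 4696020),  # unann
    nrow = 7L, byrow = TRUE, dimnames = list(classes, libs))
  tot <- matrix(c(
    14733335, 15506383, 15280087, 18331641,
    2821727,  3977020,  3062256,  2373591,
    457104,   787545,   1192127,  1345407,
    3938,     5906,     3784,     4388,
    1482,     1518,     1131,     1604,
    455610,   757135,   893294,   1084590,
    10993474, 9977259,  10127495, 13522061),
    nrow = 7L, byrow = TRUE, dimnames = list(classes, libs))
  list(unique = uq, total = tot,
       common_unique = c(PA2_PA2H = 1117707, PA4_PA4H = 810204))
}
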