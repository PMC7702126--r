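#' Embedded experimental coupling data for the quinolizidine test compound
#'
#' The package ships the published one-bond C-H coupling data of a
#' seven-stereocenter reserpine-derived quinolizidine alkaloid that serves as
#' the worked example throughout:
#' \describe{
#'   \item{\code{rd1CouplingTable()}}{all 21 measured RDCs with maximum error
#'     estimates plus three back-calculated columns (\code{d_calc_mdoc},
#'     \code{d_calc_svd_sc}, \code{d_calc_svd_mc}: trajectory-averaged,
#'     single-conformer SVD, multi-conformer SVD), as a
#'     [CouplingDataset-class].}
#'   \item{\code{rd1ScalarCouplings()}}{isotropic \eqn{^1J_{CH}} values for
#'     the CH/CH2 groups around the tertiary amine, with axial/equatorial
#'     assignments (used by [amineInversionCheck()]).}
#'   \item{\code{rd1Configurations()}}{the 32 candidate relative
#'     configurations as stereodescriptor strings over the centers C2 C3 C4
#'     C5 C6 N8 C23, with their running numbers.}
#' }
#'
#' @return see above; \code{rd1ScalarCouplings} and \code{rd1Configurations}
#'   return data.frames.
#' @examples
#' rd1CouplingTable()
#' head(rd1Configurations())
#' @export
rd1CouplingTable <- function() {
  readCouplingTable(system.file("extdata", "table3.csv", package = "RDCrank"),
                    name = "RD-1 couplings")
}

#' @rdname rd1CouplingTable
#' @export
rd1ScalarCouplings <- function() {
  utils::read.csv(system.file("extdata", "table1.csv", package = "RDCrank"),
                  stringsAsFactors = FALSE)
}

#' @rdname rd1CouplingTable
#' @export
rd1Configurations <- function() {
  tab <- utils::read.table(
    system.file("extdata", "table2_configs.txt", package = "RDCrank"),
    col.names = c("id", "descriptor"), comment.char = "#",
    stringsAsFactors = FALSE)
  tab
}
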