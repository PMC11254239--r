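#' Published cohort composition the simulator mirrors
#'
#' Cell counts of the multicenter rectal-cancer study whose design this
#' package emulates: a training cohort and an external test cohort, each
#' split into microsatellite-stable (MSS) and microsatellite-instable (MSI)
#' patients. These four counts parameterize the simulator's default MSI
#' prevalence and are the input to the prevalence arithmetic reported by the
#' acceptance script.
#'
#' @return A tibble with columns `cohort`, `msi_status` and `n`.
#' @export
#' @examples
#' counts <- reference_cohort_counts()
#' sum(counts$n)                       # 475 patients
#' with(counts, sum(n[msi_status == "MSI"]) / sum(n))  # MSI prevalence
reference_cohort_counts <- function() {
  tibble::tibble(
    cohort = c("training", "training", "external_test", "external_test"),
    msi_status = c("MSS", "MSI", "MSS", "MSI"),
    n = c(348L, 34L, 74L, 19L)
  )
}
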