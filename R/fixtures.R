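#' Named deterministic simulation fixtures
#'
#' Small bundled cohorts used throughout the test-suite and examples.
#' Regeneration is byte-identical across runs (fixed seeds inside):
#' \describe{
#'   \item{conserved7}{seven genomes, shared gene order, mixed intron
#'     sharing (the default study-like cohort)}
#'   \item{transposed}{as conserved7, but one genome carries cox2
#'     relocated between nad4 and atp8 (a planted transposition)}
#'   \item{intron_rich}{seven genomes with high intron gain}
#'   \item{intron_poor}{seven genomes with low intron gain}
#'   \item{size_gradient}{intron_rich + intron_poor combined (14 genomes,
#'     ids suffixed), for size-correlation analyses}
#' }
#'
#' @param name fixture name
#' @return a `sim_result` (see [simulate_mitogenomes()]); for
#'   `size_gradient`, records/truth are concatenated from the two cohorts
#' @export
make_fixture <- function(name = c("conserved7", "transposed", "intron_rich",
                                  "intron_poor", "size_gradient")) {
  name <- match.arg(name)
  if (name == "conserved7") {
    return(simulate_mitogenomes(simulation_config(seed = 20250124)))
  }
  if (name == "transposed") {
    moved <- c("cox1", "nad1", "nad4", "cox2", "atp8", "atp6", "rns",
               "cox3", "nad6", "rnl", "rps3", "nad2", "nad3", "atp9",
               "nad4L", "nad5", "cob")
    return(simulate_mitogenomes(simulation_config(
      seed = 20250124, order_overrides = list(G = moved))))
  }
  if (name == "intron_rich") {
    return(simulate_mitogenomes(simulation_config(
      seed = 777001, intron_gain_rate = 10, ancestral_introns = 18)))
  }
  if (name == "intron_poor") {
    return(simulate_mitogenomes(simulation_config(
      seed = 777002, intron_gain_rate = 1, ancestral_introns = 3)))
  }
  rich <- make_fixture("intron_rich")
  poor <- make_fixture("intron_poor")
  relabel <- function(sim, suffix) {
    purrr::map(sim$records, function(r) {
      r$id <- paste0(r$id, suffix); r$organism <- r$id; r
    })
  }
  comp <- dplyr::bind_rows(
    dplyr::mutate(rich$truth$components,
                  species_id = paste0(.data$species_id, "_rich")),
    dplyr::mutate(poor$truth$components,
                  species_id = paste0(.data$species_id, "_poor")))
  structure(list(records = c(relabel(rich, "_rich"), relabel(poor, "_poor")),
                 truth = list(components = comp),
                 config = list(rich = rich$config, poor = poor$config)),
            class = "sim_result")
}
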