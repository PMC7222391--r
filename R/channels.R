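#' The 32-channel EEG montage used as network nodes
#'
#' Channel names and order of the DEAP preprocessed release's 32 EEG
#' electrodes (international 10-20 placement). These 32 scalp electrodes
#' are the nodes of every network the package builds.
#'
#' @return character vector of 32 channel names.
#' @examples
#' deap_channels()[1:4]
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

default_channel_names <- function(n) {
  if (n == 32L) deap_channels() else sprintf("ch%02d", seq_len(n))
}
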