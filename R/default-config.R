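# Shipped default model configuration.
#
# The numeric tables below are the frozen result of the package's one-off
# calibration of the 33-cell rabbit AV-node network (see CALIBRATION.md at
# the repository root and the methods vignette).  They encode the graded
# distributions of refractoriness, coupling coefficient d and coupling
# asymmetry alpha along the two rows of the network.  Do not edit by hand;
# derive variants via read_avn_config()/write_avn_config().

#' Default rabbit AV-node model configuration
#'
#' Returns the shipped, calibrated parameter set for the 33-cell
#' dual-pathway network: one row per cell with its Aliev-Panfilov
#' coefficients and voltage-rescaling zone, a junction table with coupling
#' coefficient `d` (1/s) and asymmetry `alpha`, and the stimulus entry
#' points (anterograde atrial site, retrograde His site,
#' fibrillation/flutter site).
#'
#' @return a configuration list with elements `cells`, `junctions`,
#'   `entry`.
#' @seealso [build_topology()], [read_avn_config()]
#' @export
default_config <- function() {
  cells <- data.frame(
    label = c("SN", "PS1", "PS2", "PS3", "AM1", "AM2", "AM3", "FP1", "FP2", "FP3",
              "FP4", "FP5", "FP6", "FP7", "FP8", "PB", "HB1", "HB2",
              "HB3", "HB4", "HB5", "HB6", "SP1", "SP2", "SP3", "SP4",
              "SP5", "SP6", "SP7", "SP8", "SP9", "SP10", "AM*"),
    zone = c("atrial", "atrial", "atrial", "atrial", "atrial", "atrial", "atrial",
             "atrial", "atrial", "atrial", "atrial", "atrial", "atrial",
             "atrial", "atrial", "his", "his", "his", "his", "his",
             "his", "his", "atrial", "atrial", "atrial", "atrial",
             "atrial", "atrial", "atrial", "atrial", "atrial", "atrial",
             "atrial"),
    k = c( 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 7.46875, 7.46875, 8, 8, 8,
          8, 8, 8, 8.075, 8.075, 8.075, 8.075, 8.075, 8.075, 7.46875, 8,
          7.46875, 7.46875, 8),
    a1 = c(-0.038181640625, 0.15, 0.14, 0.1, 0.071, 0.071, 0.071, 0.13, 0.13,
           0.13, 0.13, 0.13, 0.13, 0.13, -0.0005, -0.0005, 0.14125,
           0.14125, 0.14125, 0.14125, 0.14125, 0.14125, 0.1, 0.1, 0.1,
           0.1, 0.1, 0.1, -0.0005, -0.0328563049316, -0.0005, -0.0005,
           0.071),
    a2 = c( 0.15, 0.15, 0.14, 0.1, 0.071, 0.071, 0.071, 0.13, 0.13, 0.13, 0.13,
           0.13, 0.13, 0.13, 0.295, 0.295, 0.14125, 0.14125, 0.14125,
           0.14125, 0.14125, 0.14125, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
           0.295, 0.15, 0.295, 0.295, 0.071),
    mu1 = c( 0.2, 0.06, 0.06, 0.1, 0.1, 0.1, 0.1, 0.06, 0.06, 0.06, 0.06, 0.06,
            0.06, 0.06, 0.1225, 0.1025, 0.06, 0.06, 0.06, 0.06, 0.06,
            0.06, 0.022625, 0.022625, 0.022625, 0.022625, 0.022625,
            0.022625, 0.022625, 0.1, 0.022625, 0.022625, 0.1),
    mu2 = c( 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3,
            0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3,
            0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    eps0 = c( 0.005, 0.004, 0.01, 0.05, 0.08, 0.08, 0.08, 0.0135, 0.0115, 0.0095,
             0.0085, 0.0075, 0.0075, 0.0095, 0.032, 0.019, 0.01005,
             0.01005, 0.01055, 0.01105, 0.01155, 0.01205, 0.075, 0.075,
             0.075, 0.075, 0.075, 0.075, 0.02, 0.06475, 0.02, 0.02, 0.08),
    ct = c( 200, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300,
           300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300, 300,
           300, 300, 300, 300, 300, 300, 300),
    stringsAsFactors = FALSE
  )
  rownames(cells) <- cells$label
  junctions <- data.frame(
    from = c("SN", "PS1", "PS2", "PS3", "AM1", "AM2", "AM3", "FP1", "FP2", "FP3",
             "FP4", "FP5", "FP6", "FP7", "FP8", "PB", "HB1", "HB2",
             "HB3", "HB4", "HB5", "AM3", "SP1", "SP2", "SP3", "SP4",
             "SP5", "SP6", "SP7", "SP8", "SP9", "SP10", "AM*"),
    to = c("PS1", "PS2", "PS3", "AM1", "AM2", "AM3", "FP1", "FP2", "FP3", "FP4",
           "FP5", "FP6", "FP7", "FP8", "PB", "HB1", "HB2", "HB3", "HB4",
           "HB5", "HB6", "SP1", "SP2", "SP3", "SP4", "SP5", "SP6", "SP7",
           "SP8", "SP9", "SP10", "PB", "AM3"),
    d = c(48.7392346139, 40.6160288449, 44.6776317294, 64.9856461519, 230, 230,
          60.5652681146, 65.6404011825, 69.9664917621, 74.2925823417,
          78.6186729213, 82.9447635009, 87.2708540805, 91.5969446602,
          77.2219098052, 53.4580063937, 53.4580063937, 53.4580063937,
          53.4580063937, 53.4580063937, 53.4580063937, 108.5, 58, 58, 58,
          58, 58, 58, 58, 85, 75, 109.375, 230),
    alpha = c( 1, 1, 1, 1, 1, 1, 0.85, 0.676875, 0.676875, 0.676875, 0.676875,
              0.676875, 0.676875, 0.676875, 0.65, 0.65, 0.65, 0.8, 1, 1,
              1, 0.61875, 0.7075, 0.7075, 0.7075, 0.7075, 0.7075, 0.4225,
              0.4225, 0.4225, 0.4225, 0.79125, 1),
    stringsAsFactors = FALSE
  )
  list(cells = cells, junctions = junctions,
       entry = list(antero = "AM1", retro = "HB1", af = "AM*"))
}
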