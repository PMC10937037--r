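Package: oscicycle
Title: Structural Conditions for Oscillations in Excitatory-Inhibitory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and simulating oscillations in networks of
    excitatory and inhibitory populations. Implements the odd inhibitory cycle
    rule on signed directed graphs, fixed-point and stability analysis of
    threshold-linear networks (including the weak/strong coupling regime
    classification for single directed cycles), delayed Wilson-Cowan rate
    models of basal-ganglia motifs, a desk-scale spiking network of
    basal-ganglia populations (conductance-based LIF and AdEx neurons), and
    shared spectral metrics (Welch power spectral density, beta-band power,
    sustained-versus-transient oscillation classification). Includes the
    cortico-basal-ganglia motif-coverage analysis relating subthalamic and
    pallidal circuits to beta-band oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
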