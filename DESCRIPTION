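Package: aqpscope
Title: Aquaporin Pore Profiling, Selectivity-Filter Annotation, and
    Permeability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for substrate selectivity of aquaporin
    water channels, centred on the ammonia-permeable plant tonoplast
    aquaporin AtTIP2;1 and its comparison with water-specific channels
    such as human AQP1.  Computes sphere-fitting pore-radius profiles
    along a channel axis (HOLE-style), annotates the five-position
    extended selectivity filter (H2P, LCP, H5P, LEP, HEP) in sequences
    and structures and classifies substrate specificity, derives
    observables from molecular-dynamics-like trajectories (permeation
    event counting, collective-diffusion osmotic permeability p_f,
    hydrogen-bond profiles, number-density grids, chi1 rotamer
    populations, and umbrella-sampling free-energy profiles via WHAM),
    and analyses stopped-flow and yeast transport kinetics
    (single-exponential rate fitting, background correction, and
    specificity ratios with propagated errors).  Bundled synthetic-data
    generators provide channel structures, Brownian pore trajectories,
    umbrella-sampling windows, and stopped-flow traces with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
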