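Package: turbidmc
Title: Monte Carlo Light Propagation in Multilayered and Voxelated Turbid Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Photon-packet Monte Carlo transport for multilayered (MCML-style)
    and voxelated turbid media such as biological tissue. Supports pluggable
    scattering phase functions (Henyey-Greenstein, modified Henyey-Greenstein,
    Gegenbauer kernel, Power of Cosines, Mie and tabulated) sampled through
    inverse-CDF lookup tables, refractive-index dispersion models and Fresnel
    interface optics, optical-fiber sources and probe-tip surface layouts,
    radial/Cartesian/fiber-array detectors, volumetric energy-deposition and
    fluence accumulators with selectable stepping methods (Albedo-Weight,
    Albedo-Reject, Microscopic Beer-Lambert), photon-packet traces and
    sampling-volume computation, and spatial-frequency-domain reflectance
    transforms. Includes dataset enumeration utilities, a validation harness
    with pluggable random number generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
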