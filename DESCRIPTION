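Package: lureprox
Title: Physical and Perceptual Proximity of Deceptive Spider Lures to Flowers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how closely the colour lures of orb-web spiders
    resemble neighbouring flowers through the eyes of their dipteran prey, and
    how that perceptual proximity interacts with physical proximity to shape
    prey-interception rates. Implements reflectance-spectrum processing (LOESS
    smoothing, negative clamping, replicate averaging), a tetrachromatic fly
    opponent colourspace built on quantum catches under a D65 illuminant,
    field-record assembly with percentile-based treatment levels, Gaussian
    linear models ranked by AICc over all marginality-respecting subsets with
    Akaike weights, conditional-slope curves for interactions, factorial
    models with estimated marginal means, Tukey-adjusted contrasts and compact
    letter displays, and seeded generators for synthetic spectra and capture
    datasets so the full pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
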