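Package: sqrex
Title: Exclusion-Energy Analysis of Protein Segregation in Immune Synapse Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies size-dependent protein segregation at immune synapses from
    two-colour fluorescence images. Fits a Boltzmann exclusion-energy observation
    model (Poisson, Gaussian or Gamma photon statistics) to contact-interface and
    free-surface pixels by Markov chain Monte Carlo, estimating per-pixel exclusion
    energies of the short receptor-ligand complex and the long unbound ligand, and
    tests the square-root-energy (SQRE) linear relation predicted by quadratic
    membrane spring energies. Includes the underlying reaction-diffusion model of
    membrane-mediated segregation with linear stability analysis (dispersion
    relation, instability margin, stability curve and patternation test), a
    finite-difference simulator, close-contact patch statistics from Gaussian random
    fields, an imaging pipeline (flat-field correction, Richardson-Lucy
    deconvolution, chromatic-shift correction, 3D contour tracking and region
    extraction), and a synthetic-image generator with known ground truth for 2D
    bilayer images and 3D confocal-like stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
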