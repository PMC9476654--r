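Package: vibquant
Title: Nuclear Quantum Effects for Conformer Energetics of Flexible Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for probing conformer energetics with
    nuclear quantum effects. Provides permutationally invariant polynomial
    (PIP) potential-surface fitting in Morse variables with a
    delta-machine-learning correction layer, unbiased diffusion Monte Carlo
    for zero-point energies and ground-state walker histograms, adiabatically
    switched time-averaged semiclassical initial value representation
    (Herman-Kluk) spectral densities, and periodic discrete variable
    representation (DVR) for one- and two-dimensional hindered rotors,
    including a constrained Fourier model of geared coupled torsions.
    Synthetic model molecules and analytic reference potentials make the
    whole pipeline runnable without external electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
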