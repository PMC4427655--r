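Package: cardiosim
Title: Reduced-Order Simulation of Ischemic Mitral Regurgitation and
    Annuloplasty Device Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator of human left-ventricular function,
    ischemic mitral regurgitation, and its correction by an undersized
    annuloplasty ring with a sub-valvular element.  Implements an
    orthotropic exponential (Holzapfel-Ogden-type) passive myocardium
    law with virtual simple-shear rigs, one-dimensional exponential
    leaflet and chordae laws with bounded least-squares material
    fitting, a transmurally lumped one-fiber left ventricle coupled to
    a two-state lumped circulation driven to its limit cycle, automatic
    infarct sizing by bisection on ejection fraction, and a quasi-static
    strip model of the mitral apparatus with tension-only chordae,
    penalty contact, and a rigid annuloplasty device, yielding
    coaptation, regurgitant gap areas, and normalized chordae-force
    time courses for healthy, infarcted, and device-treated hearts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
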