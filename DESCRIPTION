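Package: ablamech
Title: Desk-Scale Electromechanical Simulation of Left-Atrial Ablation Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled cardiac electromechanics and closed-loop circulation at
    desk scale on idealized geometry, for analyzing how rule-based
    radiofrequency ablation lesion sets in the left atrium alter electrical
    activation, tissue stiffness, and downstream pumping biomarkers.
    Provides an idealized left-atrial shell generator with rule-based fiber
    fields and nested electrophysiology/mechanics tetrahedral meshes; the five
    standard ablation lesions (pulmonary vein isolation, mitral isthmus line,
    anterior line, roof line, posterior box) and their combinations as element
    masks; the Courtemanche human atrial ionic model and a reduced ventricular
    surrogate; a monodomain finite-element solver with operator splitting,
    activation-time extraction and conduction-velocity tuning; orthotropic
    hyperelastic passive mechanics with active stress, Newmark dynamics,
    pericardial contact, backward-displacement unloading and pressure-volume
    inflation; a 0D closed-loop circulation with 3D-0D volume coupling and a
    stroke-volume-difference stopping criterion; and biomarker analysis
    including the lesion-versus-ejection-fraction regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
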