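Package: lcedscan
Title: Nanodissection and Classification of Extra Densities in Cryo-EM
    Fibril Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to isolate and characterize the rod-like extra densities
    that coordinate with lysine side chains in cryo-EM maps of amyloid
    fibrils from neurodegenerative disease. Reads MRC/CCP4 density maps and
    PDB/mmCIF atomic models, estimates the helical frame (rise and twist)
    of a fibril, dissects non-protein density away from the model, grades
    occupancy strength against a contour ladder, measures axial repeat
    distances by autocorrelation, classifies cross-sectional morphology
    (Y-, X-, V-shaped, bulky duplex, three-fold symmetric), assigns
    hydrogen-bond donor/acceptor environment codes to coordinating
    residues, validates atomic-model geometry (clash score, bond geometry,
    ribose sugar puckers), and generates synthetic fibril maps with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
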