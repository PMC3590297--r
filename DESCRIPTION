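Package: hyperview
Title: Headless Molecular and Network Visualization Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable, headless toolkit for molecular and biological
    network visualization. Parses PDB coordinate files and perceives bond
    topology from interatomic distances; builds Gaussian atomic density
    grids and extracts isosurfaces by marching cubes; constructs ray-cast
    sphere and bond-hyperboloid (HyperBalls) quadrics with a continuous
    shrink parameter; renders scenes into color/depth/normal framebuffers
    with lit-sphere (matcap) shading and cut planes; traces electrostatic
    field lines through potential grids with an animated sinusoidal dash;
    lays out Cytoscape XGMML networks in 3D by node radius; and deforms
    bonded structures with a simple damped spring network. Outputs PNG
    images, Wavefront OBJ meshes, JSON field lines and multi-model PDB
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
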