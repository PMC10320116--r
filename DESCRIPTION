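Package: volseg
Title: Preprocessing, Storage and Size-Budgeted Streaming of Volumetric
    Maps and Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Server-side engine for streaming large 3D imaging data to
    lightweight clients. Reads CCP4/MRC density maps and EMDB-SFF (HDF5)
    volume and mesh segmentations, builds multiscale downsampling pyramids
    with per-level statistics, persists them as chunked compressed arrays
    in a Zarr-layout store with JSON metadata and biological annotations,
    and answers box queries under a caller-declared point budget by
    choosing a pyramid level and packing the result as BinaryCIF
    (columnar encodings over a MessagePack container). Includes a
    deterministic synthetic-data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    httpuv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
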