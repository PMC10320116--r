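---
title: "Streaming volumetric maps and segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming volumetric maps and segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volseg)
```

## The problem

Interactive visualization of 3D imaging data — cryo-EM density maps,
volume-EM stacks, light-microscopy volumes — together with their
segmentations requires a server that can answer "give me this region of
this dataset, but no more than N values" quickly, for datasets far
larger than any single response. `volseg` implements that data plane:
ingest of the two community formats (CCP4/MRC maps, EMDB-SFF
segmentations), a multiscale chunked store, and a size-budgeted query
layer with a compact columnar wire format (BinaryCIF). The 3D rendering
client is out of scope; `decodeResponse()` is the reference decoder
that stands in for it in tests.

## Ingest

**Maps.** `readMap()` handles the MRC2014 dialect: 1024-byte header,
modes 0 (int8), 1 (int16), 2 (float32), plus 6 (uint16) read-only.
Endianness comes from the machine stamp, with a fallback heuristic
(plausible dimensions and mode after byte swap) because deposited maps
are not always well stamped. Storage axis order (MAPC/MAPR/MAPS) is
normalized so that in-memory data are always indexed `[x, y, z]`; all
external coordinates in this package are 0-based, half-open voxel
ranges on that canonical grid. Two deliberate dialect choices:

- *Header statistics are never trusted.* Deposited maps frequently
  carry stale DMIN/DMAX/DMEAN; statistics are always recomputed from
  the voxel data in double precision (population sigma).
- *Origin resolution.* The ORIGIN header fields win when any is
  nonzero; otherwise NXSTART/NYSTART/NZSTART scaled by the voxel size
  (the two conventions coexist in the wild). Voxel size is cell length
  over sampling count per axis, in Å.

Spacegroups other than P1 are read but ignored (no symmetry expansion);
2D stacks are out of scope.

R has no native 4-byte float, so float32 data are held as doubles
snapped to float32-representable values; this makes mode-2 write→read
round trips bit-exact, which the tests assert literally.

**Segmentations.** `readSFF()`/`writeSFF()` cover the EMDB-SFF HDF5
container in a deliberately scoped subset (version pinned as 0.8.0 in
the file): zlib-compressed, base64-wrapped lattice byte-streams
(first-axis-fastest, little-endian; stored in the smallest unsigned
integer width that holds the largest label), mesh vertex/triangle
arrays, and per-segment biological annotation — name, description,
RGBA colour, external references. One structural choice: meshes live in
a top-level `mesh_list` with segments referencing mesh ids, mirroring
the package's in-memory model. Shape-primitive segmentations, XML/JSON
encodings, and application-specific formats (Amira, iMod, Segger) are
out of scope — conversion to EMDB-SFF is assumed upstream. Files
declaring a non-identity lattice transform are rejected outright rather
than silently mis-registered. Segments lacking a colour get a
deterministic golden-angle palette colour indexed by segment id, so
repeated preprocessing runs agree.

## Multiscale pyramid

Levels are power-of-two factors starting at 1 (the original,
bit-identical). `planLevels(dims, minExtent, maxTotalVoxels)` adds a
level while the previous level still holds at least `maxTotalVoxels`
voxels and halving again keeps the largest axis at or above
`minExtent`; a grid whose largest axis would collapse to a single voxel
is never halved. Defaults: `minExtent = 32` voxels,
`maxTotalVoxels = 2^22` (≈4.2M voxels, 16 MiB as float32) — chosen so
that a typical streaming response at the coarsest level stays in the
low megabytes; both are tunable per entry.

Kernels (the choice is isolated in this module so it can be swapped):

- **Intensities: 2×2×2 box mean.** Output dims are `ceiling(d/2)`;
  partial blocks at odd boundaries average only existing voxels — no
  invented padding. For even dimensions this conserves the global mean
  to floating-point accuracy (asserted at 1e-6 relative).
- **Labels: majority vote**, ties broken toward the *smaller* label
  (deterministic and independent of traversal order); background 0
  participates like any label. Interval averaging would destroy label
  identity; majority voting guarantees the downsampled label set is a
  subset of the original's.

Both kernels are property-tested against deliberately naive triple-loop
implementations on random grids, including odd-dimension edge cases.
Anisotropic factors and smoothing kernels (Gaussian, Lanczos) are
non-goals; meshes are stored single-resolution.

## The store

One directory per `(source, entry_id)` (keys sanitized to
`[a-z0-9_-]`): volume and per-lattice pyramids as chunked (default
64³), zlib-compressed arrays in the Zarr v2 on-disk layout (`.zarray`
JSON + `i.j.k` chunk files, order "F" to match R's memory layout), with
`metadata.json` (dims, voxel size, origin, factors, per-level stats and
label histograms, mesh inventory, `format_version`) and
`annotations.json` (segment records) as diffable sidecars the service
can serve verbatim. JSON doubles are written with 17 significant
digits, so statistics and colours round-trip bit-exactly. Box reads
touch only the chunks the box intersects. Different segmentations of
the same map are simply different entries — the store imposes no
sharing — which is what lets clients compare segmentation outcomes side
by side. Single-writer, many-reader; no remote object-store backends.

## Queries and the wire format

`chooseLevel()` returns the smallest factor `f` with
`prod(ceiling(boxDims/f)) <= maxPoints`, falling back to the coarsest
level with a `budgetExceeded` flag. The budget is expressed in *points*
(values), not bytes, keeping the contract codec-independent; a
byte-based budget layers on top by dividing by bytes per point. The
level-space box is `[floor(lo/f), ceiling(hi/f))`, so the returned
region always covers the request. Increasing the budget never yields a
coarser factor (property-tested).

Responses are BinaryCIF: categories of named columns, each column a
byte payload plus an explicit chain of encodings, inside a MessagePack
envelope. Default chains:

- volume floats → interval quantization (255 steps over the level's
  `[min, max]`) → delta → integer packing; worst-case reconstruction
  error `(max − min)/508`, asserted in tests;
- labels → run length → delta → integer packing (lossless);
- strings → dictionary with offset table; absent values index −1.

Integer packing picks 1-byte/2-byte, signed/unsigned by measuring the
packed size and falls back to plain int32 when packing would not pay.
All intermediate integers are checked against the 32-bit range —
refusal rather than silent wraparound. Every integer chain is
round-trip-tested against straightforward R oracles (prefix sums,
`rle`, exhaustive unpack loops).

The HTTP surface (`serveEntries()`, requiring httpuv) is a thin shell
over these functions: `GET /v1/{source}/{id}/metadata`,
`.../volume/box/{lo}/{hi}?max_points=N`,
`.../segmentation/{lattice}/box/...`, `.../mesh`; errors are structured
JSON with stable codes. The default budget when omitted is 10^6 points.
Authentication, caching and CORS tuning are non-goals.

## Synthetic data

The generator exists so every pipeline stage is testable offline, and
its defaults define the conditions the test suite runs under: a 64³
voxel grid, 3 Gaussian blobs (amplitudes 0.5–2, widths between 1/10 and
1/5 of the grid), additive Gaussian noise with σ = 0.05, 3
non-overlapping digital spheres (membership: voxel center strictly
within radius) labeled 1..n with `segment_k` names, palette colours and
a synthetic GO external reference, and one icosphere mesh
(`V = 10·4^s + 2`, `T = 20·4^s`, Euler characteristic 2) scaled into
the volume box. All randomness flows from a single seed through a
private RNG stream, so fixtures are bit-reproducible.

What the generator does *not* emulate — and hence what passing tests do
not show: realistic density from atomic models, experimental noise
spectra and artifacts (CTF, missing wedge), anisotropic voxels,
irregular segment shapes, or multi-gigavoxel scale. The tests establish
format fidelity, algorithmic correctness, and the budget contract, not
biological realism or large-scale throughput.

## Numerical and degenerate-input choices

- Constant volumes quantize over a degenerate range; the encoder widens
  `[lo, lo]` to `[lo, lo+1]`, so constants decode exactly.
- Empty grids, empty boxes after clamping, non-positive budgets,
  dangling lattice references, and metadata/array disagreements all
  raise typed errors (`empty grid`, `empty region`, `invalid budget`,
  `dangling lattice`, `corrupt entry`) rather than degrading silently.
- Test problem sizes are desk-scale by design: random grids of 3–9
  voxels per axis for format round trips, 8³–64³ for pyramid and
  end-to-end checks, a ~10⁴-case exhaustive grid for level selection.

## Known limitations

Crystallographic symmetry, OME-NGFF input, mesh decimation, shape
primitives, byte-denominated budgets and concurrent writers are all out
of scope. The EMDB-SFF subset is pinned to one schema layout; files
from other schema versions may need conversion. The HTTP layer is
single-threaded R — adequate for local sharing, not for production
traffic.
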