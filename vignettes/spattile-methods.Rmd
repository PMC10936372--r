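---
title: "spattile methods: pyramids, chunked stores, and converters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spattile methods: pyramids, chunked stores, and converters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of how its pieces work and why
they are shaped the way they are: the tiled-pyramid file layout, the
resampling and filtering mathematics, the chunked feature store, the Sample
folder schema, the converters, and what the synthetic fixtures do and do
not emulate.

## The problem

Spatially resolved transcriptomics pairs large microscope images with
per-location feature matrices. An H&E scan under a 10x Visium slide or a
stitched MERFISH mosaic easily exceeds 20,000 × 20,000 pixels; gene panels
run from tens to tens of thousands of features. A viewer should be able to
show any region at any zoom, and color it by any one feature, while
fetching only a tiny fraction of the stored bytes — whether the data sit
on local disk or behind a web server that supports HTTP range requests.

Two byte layouts make that possible: a tiled multi-resolution image whose
tile index sits at the front of the file, and a column-chunked sparse
feature store whose chunk index sits at the front of the file. Everything
else in the package exists to produce, validate, or consume those layouts.

## Tile pyramids

An `ImagePlane` is an `H × W × C` array with a dtype (`uint8`, `uint16`,
`float32`) and channel names. `build_pyramid()` stacks resolution levels:
the finest level is the input, bit-identical; each coarser level is the
block-mean downsample of the next finer one; levels are added until the
coarsest fits one tile along its longest side, giving

$$ n_\text{levels} = \max\!\big(1,\ \lceil \log_f (\max(W,H)/T) \rceil + 1 \big) $$

for tile size $T$ (default 512) and integer factor $f$ (default 2). In the
API, level 0 is the *coarsest* — the level a viewer loads first at minimum
zoom — while on disk the full-resolution image comes first, matching the
cloud-optimized GeoTIFF convention of a main image followed by
reduced-resolution subfiles. The reader maps between the two numberings.

**Resampling.** Each output pixel is the arithmetic mean of its
$f \times f$ source block; when a dimension is not a multiple of $f$ the
last row/column is replicated to fill the block, so the output has
$\lceil \cdot / f \rceil$ pixels per side and nested levels compose
exactly ($\lceil\lceil W/f\rceil/f\rceil = \lceil W/f^2\rceil$). Integer
dtypes round half-up (`floor(x + 0.5)`), which keeps the operation
oracle-checkable: an independent implementation of "mean then round"
reproduces every level exactly, except possibly the replicated edge pixels
of odd-sized levels where iterated rounding may differ by one intensity
unit. Mean was chosen because it is the standard overview resampler and
exactly verifiable; fancier kernels (Lanczos, area-weighted) are out of
scope.

The implementation aggregates with `rowsum()` over row/column groups, in
bands of at most 2048 output rows, and keeps integer planes integer
throughout — a deliberate choice so that a 20,480² image never
materializes a full-size double copy (that would be 3.4 GB on its own).

**File layout.** `write_cog()` emits a classic little-endian tiled TIFF:
an 8-byte header, then every IFD together with its external values (tile
offset/bytecount arrays, per-level dims, a JSON `ImageDescription` with
channel names and pyramid parameters), then all tile payloads. Because the
whole index lives in a contiguous front block, a reader can bootstrap from
one bounded prefix fetch: `cog_open()` reads a 16 KiB prefix and extends
it only if the index runs past it. After that, `read_tile()` costs exactly
one range request of the tile's stored size — the property the
`ByteSource` counter makes testable.

**Codecs.** Tiles are stored raw (`none`), as zlib streams (`deflate`,
TIFF compression 8; written with `memCompress`, which emits exactly the
RFC 1950 format TIFF requires), or as complete JFIF streams (`jpeg`, TIFF
compression 7, via the `jpeg` package). JPEG is restricted to 8-bit images
with 1 or 3 channels — the histology use case — and defaults to quality
90; 16-bit and multichannel immunofluorescence data default to DEFLATE.
Lossless modes round-trip bit-exactly (float32 planes are snapped to
float32 precision at construction so this holds for them too). Edge tiles
are padded to full tile size by edge replication (pleasant for JPEG,
invisible for lossless modes) and clipped on read.

Files written this way are ordinary tiled TIFFs: `tiff::readTIFF`
(libtiff) reads them back, which the test suite uses as an independent
reader oracle. No geographic CRS metadata is written — coordinates are
pixel coordinates, origin top-left, x right, y down, 0-based, with
half-open viewport rectangles in `tiles_for_viewport()`.

**Byte sources.** `open_byte_source()` abstracts local files and http(s)
URLs. Remote reads send `Range: bytes=a-b` headers; a one-byte probe at
open time detects servers that ignore `Range`, in which case the source
falls back to a single whole-file fetch, flags itself
(`supports_range = FALSE`), and serves later reads from memory. The
`bytes_read` counter records actual transfer, so the laziness bounds in
the tests are measurements, not assumptions.

## The chunked feature store (SCF1)

A `FeatureMatrix` holds `N` points × `F` features; quantitative values are
float32, categorical columns are label vectors with `NA` for "unlabeled".
`write_store()` produces:

```
"SCF1" | header length (u32 LE) | JSON header | concatenated gzip chunks
```

The header maps each feature name to `{offset, length, n_nonzero, kind}`
(plus a label dictionary for categorical features), with offsets relative
to the end of the header; it also records `n_points`, which a reader needs
to densify a column. Each chunk is a gzip-compressed CSV fragment of
`index,value` rows, zeros omitted, indices 0-based. One chunk per feature
makes the lazy bound exact and simple: reading a feature costs the header
(once per source) plus that feature's `length` bytes, and corrupting any
byte of a chunk is caught by the gzip integrity check and surfaced as a
`corrupt-chunk` error.

Values are written with 9 significant digits, which round-trips any
float32 exactly; `read_feature()` re-snaps to float32, so the chunked
round trip is the identity on float32 columns. `log_transform()` applies
$x \mapsto \ln(1 + x)$ elementwise — natural log, the dominant convention
for expression data (the base is otherwise arbitrary); zeros map to zeros,
so sparsity patterns and `n_nonzero` are preserved.

Small feature sets do not benefit from chunking: `write_features()` picks
a plain dense CSV (`id` column plus one column per feature) when
`F ≤ 50`, and the chunked store above otherwise; either can be forced.

## Sample folders

A sample is a folder with a `sample.json` manifest (schema version 1)
binding three component kinds:

* `images` — COG uri, channel names, and `m_per_px`, the physical size of
  one full-resolution pixel in metres;
* `overlays` — named point sets (CSV `id,x,y`, coordinates in metres) with
  a geometry kind (`circle` with a physical diameter, `point`, `polygon`);
* `feature_groups` — feature files bound to an overlay by name, with
  storage (`chunked`/`plain`) and data kind.

Physical units are metres: that makes a Visium spot diameter a clean
`55e-6` and leaves pixel scale as a single multiplicative factor per
image. Coordinates and features are separated on purpose — the dependency
is one-way, so deleting a feature group can never invalidate an overlay,
and several feature groups can share one overlay without duplicating
positions. `validate_sample()` enforces the referential rules (every uri
resolves, feature counts equal overlay point counts, store headers parse,
chunks decompress) as errors, and flags out-of-bounds overlay points as
warnings — real Visium slides routinely have spots off the tissue, so
that is not an error.

## Converters

**Visium.** `read_visium_run()` ingests Space Ranger *filtered* output:
Matrix Market counts with barcodes/features tables (root or
`filtered_feature_bc_matrix/`, plain or gzipped), tissue positions in both
CSV dialects (headerless `tissue_positions_list.csv` and headered
`tissue_positions.csv`), `scalefactors_json.json`, and the
full-resolution TIFF. `convert_visium()` then:

1. optionally Gaussian-filters the image (default σ = 4 px, see below)
   and writes the COG (JPEG for 8-bit 1/3-channel images, DEFLATE
   otherwise);
2. derives the physical scale from the one constant the platform fixes —
   a capture spot is 55 µm across, and Space Ranger reports its pixel
   diameter, so `m_per_px = 55e-6 / spot_diameter_fullres`;
3. writes the `spots` overlay (circles, diameter `55e-6` m) at each
   in-tissue barcode's full-resolution position, in matrix barcode order;
4. writes `ln(1 + count)` per gene per spot as a chunked store.

Only in-tissue barcodes are kept (the filtered matrix defines the set); a
matrix barcode without a position row is a consistency error.
Visium-SPG — multiplex immunofluorescence protein imaging paired with
gene expression — uses the same path with a multichannel image and
per-channel names (e.g. NeuN, TMEM119, GFAP, OLIG2); nothing else differs.

The Gaussian pre-filter is a separable convolution with a normalized
kernel, σ = `radius`, truncated at 3σ, edge-replicated borders; radius 0
is the identity. "Radius" is interpreted as σ — the convention is
genuinely ambiguous in common tooling, and σ with 3σ support is the
interpretation that makes the impulse response directly checkable against
the analytic kernel.

**MERFISH.** `read_merfish_run()` ingests the Vizgen release trio
(`cell_by_gene.csv`, `cell_metadata.csv` with micron centroids, the 3×3
micron→mosaic-pixel affine) plus the mosaic TIFF, taking the *first*
z-plane as the viewing background. `convert_merfish()` maps centroids
through the affine (homogeneous multiply, singular matrices rejected),
writes them as a `point` overlay, and stores per-cell counts raw —
`log1p = TRUE` opts into the natural-log transform, mirroring the
asymmetry that sequencing-based counts are conventionally log-viewed while
imaging-based molecule counts often are not. The mosaic pixel's physical
size comes from the affine's linear part
(`px_per_um = sqrt(|det A₂ₓ₂|)`, assuming near-uniform scale).

## Annotations

Annotations exist at three granularities: per-point labels (spots or
cells; CSV `id,label`), labeled region polygons (spatial domains; GeoJSON
`Polygon` features with a `label` property, rings explicitly closed on
export), and labeled point markers (GeoJSON `Point` features). GeoJSON
coordinates here are full-resolution *pixel* coordinates with y growing
downward; the files say so in a top-level `crs_note`, because silently
reusing the geographic convention would invert microscopy data. Exports
are deterministic (fixed key order and number formatting), imports accept
files from other tools (missing labels become `"unlabeled"`, unsupported
geometry types are skipped with a warning, polygon holes are dropped with
a warning).

`assign_points_to_regions()` uses even-odd ray casting with an on-edge
short circuit, so boundaries count as inside — a spot centred exactly on
a domain border should be annotated, not dropped, and inclusivity makes
the result stable under coordinate rounding. When regions overlap, the
region listed last wins, matching the "latest annotation overrides"
intuition of interactive use. The test suite checks the whole predicate
against an independent winding-number oracle on random convex polygons.

## Synthetic fixtures: what they do and do not show

The generators produce deterministic, seed-reproducible datasets in the
real on-disk formats, with all planted ground truth returned alongside:

* images: coarse diagonal gradient + seeded uniform noise + optional
  bright impulse markers (for filter-response tests); a 20,480² preset
  exercises the large-image path;
* Visium: spots on a hexagonal-like grid spaced at twice the spot
  diameter (loosely mimicking the real geometry), negative-binomial
  counts (mean 2, dispersion 0.5 — a standard overdispersed count model)
  thinned to a target sparsity of 20% by default, planted out-of-tissue
  position rows, both positions dialects on request;
* MERFISH: uniformly scattered micron centroids placed so their pixel
  images land in bounds, a realistic default affine (9.2593 px/µm, i.e. a
  0.108 µm mosaic pixel, with a small translation), counts at 15%
  sparsity, and a multi-z mosaic whose planes carry distinct intensity
  offsets so "which z did the converter take" is verifiable.

Default problem sizes (24 spots × 40 genes, 200 cells × 30 genes, images
around 1024²) are chosen so the full conversion pipeline, including
pyramid building and validation, runs in seconds; the capability run uses
the 20,480² preset. What passing tests show is *format and pipeline
correctness*: byte layouts, lazy-read bounds, exact fidelity of counts
and positions through conversion. What they do not show is robustness to
the messiness of real data — tissue morphology, segmentation errors,
instrument-specific metadata quirks, or files produced by other software
versions than the documented layouts.

## Numerical choices and degenerate inputs

* Integer means round half-up; iterated levels may differ from a
  one-shot oracle by ±1 only at replicated edges of odd-sized levels.
* float32 planes and feature values are snapped to float32 at
  construction, making file round trips exactly the identity.
* Tile indexes and offsets are carried as doubles (exact for files below
  2⁵³ bytes; classic TIFF caps files at 4 GiB anyway).
* Zero-sized images, non-finite feature values, negative log inputs,
  singular affines, duplicate feature names, and out-of-range tile
  addresses are rejected with typed error messages (`invalid-input`,
  `data error`, `domain error`, `invalid-transform`, `schema error`,
  `tile-address`); truncated or damaged files surface as
  `corrupt-source` / `corrupt-chunk`.
* The point-in-polygon edge test uses a relative tolerance of 1e-9 on the
  cross product; ties between overlapping regions resolve to the
  last-listed region, deterministically.

## Known limitations

* Classic (non-Big) TIFF: 4 GiB file ceiling; fine for DEFLATE/JPEG tiles
  at the documented sizes, but a very large uncompressed multichannel
  float32 pyramid could exceed it.
* One resampling kernel (block mean); no alternative overview filters.
* JPEG tiles only for 8-bit, 1- or 3-channel images.
* Polygon holes are parsed but dropped (with a warning), not treated as
  exclusions.
* The manifest schema is this package's own (version-tagged); it follows
  the published architecture of image/overlay/feature separation but is
  not byte-compatible with any external viewer's production manifests.
* Remote sources: plain http(s) with optional Range support; no
  authentication, retries, or parallel fetches.
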