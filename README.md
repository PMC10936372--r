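# spattile

Tiled image pyramids and lazy feature stores for spatial omics.

Modern spatial transcriptomics experiments pair very large microscope
images (often beyond 20,000 × 20,000 pixels — an H&E scan under a 10x
Visium capture area, or a stitched Vizgen MERFISH mosaic) with per-spot or
per-cell feature matrices such as gene expression. Viewing and sharing such
data should not require downloading gigabytes up front: a viewer that knows
*where* each tile and each feature lives inside a file can fetch exactly
the bytes it needs, from local disk or from cloud storage, with plain HTTP
range requests.

`spattile` is the preprocessing and format side of that idea, for R:

* **Tile pyramids** (`build_pyramid()`, `write_cog()`, `read_tile()`,
  `tiles_for_viewport()`) — multiscale tiled images in the cloud-optimized
  GeoTIFF (COG) layout: all tile indexes at the front of the file,
  full-resolution image first, block-mean overviews after it. Level 0 is
  the coarsest level, so a viewer opening a dataset fetches a handful of
  level-0 tiles and refines as the user zooms. Lossless DEFLATE (or none)
  and lossy JPEG (default quality 90) tile codecs.
* **Byte sources** (`open_byte_source()`, `read_bytes()`) — uniform range
  reads over local files and http(s) URLs with an instrumented
  `bytes_read` counter, so laziness is a measured property, not a promise.
* **Sparse chunked feature stores** (`write_store()`, `read_feature()`) —
  each feature (e.g. one gene) is a gzip-compressed sparse CSV chunk behind
  a JSON index header; reading one gene across all spots costs one range
  request. Plain dense CSV is used automatically for small feature sets.
* **Sample folders** (`write_sample()`, `validate_sample()`) — a
  `sample.json` manifest binding images, overlays (named sets of spatial
  points in physical units, metres) and feature groups. Coordinates and
  features are deliberately separate: overlays own positions, feature
  groups reference overlays by name.
* **Converters** (`convert_visium()`, `convert_merfish()`) — 10x Space
  Ranger filtered output (Matrix Market counts, tissue positions, scale
  factors, full-resolution TIFF) and Vizgen MERFISH release files
  (cell-by-gene CSV, micron centroids, 3×3 micron→mosaic-pixel affine,
  multi-z mosaic) to Sample folders. Visium spots become 55 µm circles
  with `m_per_px = 55e-6 / spot_diameter_fullres`; counts are stored as
  `ln(1 + x)` for Visium (raw for MERFISH); images are Gaussian
  pre-filtered (σ = 4 px by default) before pyramid building; the MERFISH
  background is the first z-plane of the mosaic.
* **Annotations** (`export_annotations()`, `import_annotations()`,
  `assign_points_to_regions()`) — labels at cell/spot level (CSV
  `id,label`) and spatial-domain level (GeoJSON polygons in pixel
  coordinates), plus boundary-inclusive point-in-polygon assignment of
  overlay points to labeled regions.
* **Fixtures** (`make_image_fixture()`, `make_visium_fixture()`,
  `make_merfish_fixture()`) — deterministic synthetic datasets in all the
  supported on-disk formats, with planted ground truth, so everything
  above is testable offline.

## Worked example

```r
library(spattile)

fixture    <- make_visium_fixture(seed = 7, dir = tempfile())
run        <- read_visium_run(fixture$dir, fixture$image_path)
run
#> VisiumRun: 40 gene(s) x 24 barcode(s), image 1024 x 1024

sample_dir <- tempfile("sample")
convert_visium(run, sample_dir, compression = "deflate")
validate_sample(sample_dir)
#> sample valid

md <- read_sample(sample_dir)
md$overlays[[1]]$diameter      # Visium spots are 55 micron circles
#> [1] 5.5e-05
md$images[[1]]$m_per_px        # 55e-6 m / 80 px spot diameter
#> [1] 6.875e-07

cog_open(file.path(sample_dir, "image.tif"))
#> COG .../image.tif: 1024 x 1024, 3 channel(s), 2 level(s), tile 512

src <- open_byte_source(file.path(sample_dir, "genes.scf"))
v   <- read_feature(src, "GENE007")   # ln(1 + count) per spot
sum(v > 0)
#> [1] 3
bytes_read(src)                       # header + one chunk, not the file
#> [1] 3039
```

The last numbers are the point of the architecture: the store is 5,453
bytes, and reading one gene transferred 3,039 (index header plus that
gene's chunk). On a real dataset with thousands of genes the same two
range requests still fetch only the header and one chunk.

A thin command-line front end over the same functions lives in
`inst/cli/spattile.R`:

```sh
Rscript inst/cli/spattile.R synth  --preset visium --seed 4 --out demo
Rscript inst/cli/spattile.R visium demo --image demo/image.tif --out sample
Rscript inst/cli/spattile.R validate sample
```

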