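#!/bin/sh
# Fetch the deposited data sets used by the accession-based checks into
# inst/extdata/deposited/ (network required).
set -e
dir="$(dirname "$0")/../inst/extdata/deposited"
mkdir -p "$dir"
curl -fsSL -o "$dir/8H8H.pdb" https://files.rcsb.org/download/8H8H.pdb
curl -fsSL -o "$dir/5B52.pdb" https://files.rcsb.org/download/5B52.pdb
# SASBDB: averaged subtracted sample profile for SASDUP4
curl -fsSL -o "$dir/SASDUP4.dat" \
  "https://www.sasbdb.org/media/intensities_files/SASDUP4.dat"
echo "done; files in $dir"
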