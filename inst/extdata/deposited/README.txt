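Drop-in location for deposited data sets that are not redistributed with
the package:

  8H8H.pdb or 8H8H.cif   crystal structure of the bent N-terminal domain
                         (eight chains, four terminal-site dimers)
  5B52.pdb or 5B52.cif   crystal structure of the oligomerization-deficient
                         R8A variant (central-site dimer, elongated helix)
  SASDUP4.dat            background-subtracted, peak-averaged SEC-SAXS
                         profile (3 columns: Q [1/A], I, sigma)

Run scripts/fetch_deposited.sh from the repository root (requires network)
to download them, or place the files here by hand.  depositedFile("8H8H")
locates them; options(mvatkit.depositedDir=...) points at an alternative
directory.
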