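model: huh7_hypoxia
metabolites:
  - id: Glc.x
    compartment: extracellular
    carbons: 6
    balanced: no
  - id: Gln.x
    compartment: extracellular
    carbons: 5
    balanced: no
  - id: Cit.x
    compartment: extracellular
    carbons: 6
    balanced: no
  - id: Lac.x
    compartment: extracellular
    carbons: 3
    balanced: no
  - id: Glu.x
    compartment: extracellular
    carbons: 5
    balanced: no
  - id: CO2
    compartment: extracellular
    carbons: 1
    balanced: no
  - id: Glc.c
    compartment: cytosol
    carbons: 6
    balanced: yes
  - id: GAP
    compartment: cytosol
    carbons: 3
    balanced: yes
  - id: Pyr.c
    compartment: cytosol
    carbons: 3
    balanced: yes
  - id: Pyr.m
    compartment: mitochondrion
    carbons: 3
    balanced: yes
  - id: AcCoA.m
    compartment: mitochondrion
    carbons: 2
    balanced: yes
  - id: AcCoA.c
    compartment: cytosol
    carbons: 2
    balanced: yes
  - id: Cit.m
    compartment: mitochondrion
    carbons: 6
    balanced: yes
  - id: Cit.c
    compartment: cytosol
    carbons: 6
    balanced: yes
  - id: aKG.m
    compartment: mitochondrion
    carbons: 5
    balanced: yes
  - id: aKG.c
    compartment: cytosol
    carbons: 5
    balanced: yes
  - id: Suc.m
    compartment: mitochondrion
    carbons: 4
    balanced: yes
  - id: Fum.m
    compartment: mitochondrion
    carbons: 4
    balanced: yes
  - id: Mal.m
    compartment: mitochondrion
    carbons: 4
    balanced: yes
  - id: Mal.c
    compartment: cytosol
    carbons: 4
    balanced: yes
  - id: OAA.m
    compartment: mitochondrion
    carbons: 4
    balanced: yes
  - id: OAA.c
    compartment: cytosol
    carbons: 4
    balanced: yes
  - id: Glu.m
    compartment: mitochondrion
    carbons: 5
    balanced: yes
  - id: Glu.c
    compartment: cytosol
    carbons: 5
    balanced: yes
  - id: Gln.c
    compartment: cytosol
    carbons: 5
    balanced: yes
  - id: Asp.m
    compartment: mitochondrion
    carbons: 4
    balanced: yes
  - id: Asp.c
    compartment: cytosol
    carbons: 4
    balanced: yes
  - id: Palm.c
    compartment: cytosol
    carbons: 16
    balanced: yes
reactions:
  - id: GLC_UP
    eq: Glc.x (abcdef) -> Glc.c (abcdef)
    reversible: no
    bounds:
      - 0.0
      - 500.0
  - id: GLYC
    eq: Glc.c (abcdef) -> GAP (cba) + GAP (def)
    reversible: no
    bounds:
      - 0.0
      - 500.0
  - id: PK
    eq: GAP (abc) -> Pyr.c (abc)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: LDH
    eq: Pyr.c (abc) -> Lac.x (abc)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: PYT
    eq: Pyr.c (abc) -> Pyr.m (abc)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: PDH
    eq: Pyr.m (abc) -> CO2 (a) + AcCoA.m (bc)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: PC
    eq: Pyr.m (abc) + CO2 (d) -> OAA.m (abcd)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: CS
    eq: OAA.m (abcd) + AcCoA.m (ef) -> Cit.m (efabcd)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: IDHM
    eq: Cit.m (abcdef) -> aKG.m (cabde) + CO2 (f)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: IDHC
    eq: Cit.c (abcdef) -> aKG.c (cabde) + CO2 (f)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: AKGDH
    eq:
      - aKG.m (abcde) -> CO2 (a) + Suc.m (bcde)
      - aKG.m (abcde) -> CO2 (a) + Suc.m (edcb)
    weights:
      - 0.5
      - 0.5
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: SDH
    eq:
      - Suc.m (abcd) -> Fum.m (abcd)
      - Suc.m (abcd) -> Fum.m (dcba)
    weights:
      - 0.5
      - 0.5
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: FUM
    eq:
      - Fum.m (abcd) -> Mal.m (abcd)
      - Fum.m (dcba) -> Mal.m (abcd)
    weights:
      - 0.5
      - 0.5
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: MDHM
    eq: Mal.m (abcd) -> OAA.m (abcd)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: MDHC
    eq: Mal.c (abcd) -> OAA.c (abcd)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: MEM
    eq: Mal.m (abcd) -> Pyr.m (abc) + CO2 (d)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: MEC
    eq: Mal.c (abcd) -> Pyr.c (abc) + CO2 (d)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: ACLY
    eq: Cit.c (abcdef) -> AcCoA.c (ab) + OAA.c (cdef)
    reversible: no
    bounds:
      - 0.0
      - 2000.0
  - id: FAS
    eq: AcCoA.c (ab) + AcCoA.c (cd) + AcCoA.c (ef) + AcCoA.c (gh) + AcCoA.c (ij) +
      AcCoA.c (kl) + AcCoA.c (mn) + AcCoA.c (op) -> Palm.c (abcdefghijklmnop)
    reversible: no
    bounds:
      - 0.0
      - 100.0
  - id: FAO
    eq: Palm.c (abcdefghijklmnop) -> AcCoA.m (ab) + AcCoA.m (cd) + AcCoA.m (ef) +
      AcCoA.m (gh) + AcCoA.m (ij) + AcCoA.m (kl) + AcCoA.m (mn) + AcCoA.m (op)
    reversible: no
    bounds:
      - 0.0
      - 50.0
  - id: PALM_OUT
    eq: 'Palm.c -> '
    reversible: no
    bounds:
      - 0.0
      - 100.0
  - id: GLN_UP
    eq: Gln.x (abcde) -> Gln.c (abcde)
    reversible: no
    bounds:
      - 0.0
      - 500.0
  - id: GLS
    eq: Gln.c (abcde) -> Glu.m (abcde)
    reversible: no
    bounds:
      - 0.0
      - 500.0
  - id: GDH
    eq: Glu.m (abcde) -> aKG.m (abcde)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: GOT2
    eq: OAA.m (abcd) + Glu.m (efghi) -> Asp.m (abcd) + aKG.m (efghi)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: GOT1
    eq: OAA.c (abcd) + Glu.c (efghi) -> Asp.c (abcd) + aKG.c (efghi)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: GLU_SEC
    eq: Glu.c (abcde) -> Glu.x (abcde)
    reversible: no
    bounds:
      - 0.0
      - 500.0
  - id: CIT_UP
    eq: Cit.x (abcdef) -> Cit.c (abcdef)
    reversible: no
    bounds:
      - 0.0
      - 200.0
  - id: MAL_T
    eq: Mal.m (abcd) -> Mal.c (abcd)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: ASP_T
    eq: Asp.m (abcd) -> Asp.c (abcd)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: GLU_T
    eq: Glu.m (abcde) -> Glu.c (abcde)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: AKG_T
    eq: aKG.m (abcde) -> aKG.c (abcde)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: CIT_T
    eq: Cit.m (abcdef) -> Cit.c (abcdef)
    reversible: yes
    bounds:
      - -2000.0
      - 2000.0
  - id: BIOMASS
    eq: '0.4 GAP + Pyr.c + 0.6 Asp.c + 0.6 Glu.c + 0.45 Gln.c + 0.05 Palm.c -> '
    reversible: no
    bounds:
      - 0.0
      - 200.0
tracers:
  - id: glc6
    metabolite: Glc.x
    positions:
      - 1
      - 2
      - 3
      - 4
      - 5
      - 6
    purity: 1.0
    fraction: 1.0
  - id: gln5
    metabolite: Gln.x
    positions:
      - 1
      - 2
      - 3
      - 4
      - 5
    purity: 1.0
    fraction: 1.0
  - id: cit24
    metabolite: Cit.x
    positions:
      - 2
      - 4
    purity: 1.0
    fraction: 1.0
fragments:
  - label: Ala
    metabolite: Pyr.c
    carbons:
      - 1
      - 2
      - 3
    formula: C11H26NO2Si2
  - label: Cit
    metabolite: Cit.c
    carbons:
      - 1
      - 2
      - 3
      - 4
      - 5
      - 6
    formula: C26H55O7Si4
  - label: AKG
    metabolite: aKG.c
    carbons:
      - 1
      - 2
      - 3
      - 4
      - 5
    formula: C14H28NO5Si2
  - label: Suc
    metabolite: Suc.m
    carbons:
      - 1
      - 2
      - 3
      - 4
    formula: C12H23O4Si2
  - label: Fum
    metabolite: Fum.m
    carbons:
      - 1
      - 2
      - 3
      - 4
    formula: C12H21O4Si2
  - label: Mal
    metabolite: Mal.m
    carbons:
      - 1
      - 2
      - 3
      - 4
    formula: C18H39O5Si3
  - label: Asp
    metabolite: Asp.c
    carbons:
      - 1
      - 2
      - 3
      - 4
    formula: C18H40NO4Si3
  - label: Glu
    metabolite: Glu.m
    carbons:
      - 1
      - 2
      - 3
      - 4
      - 5
    formula: C19H42NO4Si3

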