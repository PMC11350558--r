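# Myeloid peripheral-blood panel: 14 surface markers on 50 uL of whole
# blood, resolving granulocyte, monocyte, MDSC and dendritic-cell subsets.
#
# Gate logic notes. The original gates were drawn manually as 2-D regions;
# here each gate is a conjunction of per-channel threshold conditions
# (rectangle gates in asinh-transformed space for fluorescence, linear
# space for scatter). Thresholds without a fixed value are placed
# automatically from the sample. Nodes whose marker logic is a
# convention-based reconstruction (no authoritative gate drawing available)
# are flagged "reconstructed from convention" below.
schema_version: 1
panel:
  name: myeloid
  scatter_channels: [FSC, SSC]
  markers:
    - {marker: B220,     channel: APC5,         role: surface}
    - {marker: CCR2,     channel: PC7,          role: surface}
    - {marker: CD11b,    channel: PC5.5,        role: surface}
    - {marker: CD11c,    channel: APC7,         role: surface}
    - {marker: CD172a,   channel: VioBlue,      role: surface}
    - {marker: CD45,     channel: VioGreen,     role: surface}
    - {marker: CD49b,    channel: ECD/PE-Vio615, role: surface}
    - {marker: Ly6C,     channel: PerCP/PC5,    role: surface}
    - {marker: CD80,     channel: APC,          role: surface}
    # CD86 is co-stained with CD80 on the APC detector (combined
    # activation signal); only CD80 is used in gate conditions.
    - {marker: CD86,     channel: APC,          role: surface, costain: true}
    - {marker: F4/80,    channel: FITC,         role: surface}
    - {marker: Ly6G,     channel: BV605,        role: surface}
    - {marker: MHC-II,   channel: BV650,        role: surface}
    - {marker: Siglec-F, channel: PE,           role: surface}
gating:
  leukocyte_node: CD45_Leukocytes
  root:
    # Intact-cell gate: scatter rectangle excluding debris; bounds are in
    # linear scatter units and can be overridden per experiment.
    name: intact
    conditions:
      - {channel: FSC, relation: positive, threshold: 10000}
      - {channel: SSC, relation: positive, threshold: 1500}
    children:
      - name: CD45_Leukocytes
        reported: true
        conditions:
          - {channel: CD45, relation: positive}
        children:
          - name: CD45_Myeloid
            reported: true
            conditions:
              - {channel: CD11b, relation: positive}
            children:
              - name: Granulocytes
                reported: true
                # Side-scatter-high granular cells.
                conditions:
                  - {channel: SSC, relation: high}
                children:
                  - name: Neutrophils
                    reported: true
                    conditions:
                      - {channel: Ly6G, relation: positive}
                  - name: Eosinophils
                    reported: true
                    conditions:
                      - {channel: Ly6G, relation: negative}
                      - {channel: Siglec-F, relation: positive}
                  - name: Basophils
                    # Reconstructed from convention: CD49b+ SSC-high
                    # non-neutrophil non-eosinophil granulocytes.
                    reported: true
                    conditions:
                      - {channel: Ly6G, relation: negative}
                      - {channel: Siglec-F, relation: negative}
                      - {channel: CD49b, relation: positive}
              - name: Total_Monocytes
                reported: true
                conditions:
                  - {channel: SSC, relation: intermediate}
                  - {channel: Ly6G, relation: negative}
                  - {channel: Siglec-F, relation: negative}
                  - {channel: F4/80, relation: positive}
                children:
                  - name: Classical_Monocytes
                    reported: true
                    conditions:
                      - {channel: Ly6C, relation: high}
                      - {channel: CCR2, relation: positive}
                  - name: Non_classical_monocytes
                    reported: true
                    conditions:
                      - {channel: Ly6C, relation: low}
                      - {channel: CCR2, relation: negative}
              - name: PMN_MDSCs
                # CD11b+ Ly6G+ Ly6C-low polymorphonuclear MDSC phenotype.
                reported: true
                conditions:
                  - {channel: Ly6G, relation: positive}
                  - {channel: Ly6C, relation: low}
              - name: M_MDSCs
                # CD11b+ Ly6C-high Ly6G- monocytic MDSC phenotype;
                # F4/80- distinguishes from classical monocytes
                # (reconstructed from convention).
                reported: true
                conditions:
                  - {channel: Ly6G, relation: negative}
                  - {channel: Ly6C, relation: high}
                  - {channel: F4/80, relation: negative}
          - name: CD172a_Myeloids
            reported: true
            conditions:
              - {channel: CD172a, relation: positive}
          - name: p_DC
            # Plasmacytoid dendritic cells: CD11b- CD11c+ B220+.
            reported: true
            conditions:
              - {channel: CD11b, relation: negative}
              - {channel: CD11c, relation: positive}
              - {channel: B220, relation: positive}
            children:
              - name: Mature_pDC
                reported: true
                conditions:
                  - {channel: MHC-II, relation: positive}
          - name: cDC1
            # Conventional type-1 dendritic cells: CD11c+ MHC-II+ CD172a-.
            reported: true
            conditions:
              - {channel: CD11b, relation: negative}
              - {channel: B220, relation: negative}
              - {channel: CD11c, relation: positive}
              - {channel: MHC-II, relation: positive}
              - {channel: CD172a, relation: negative}
            children:
              - name: mature_cDC1
                reported: true
                conditions:
                  - {channel: CD80, relation: positive}
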