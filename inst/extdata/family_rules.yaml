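# Domain-combination rules defining the 11 UPS gene families.
# A protein belongs to a family if all domains of any one combination are
# present among its domain hits (E-value-filtered); domains listed under
# `excluded` never count towards that family. When a protein matches several
# families the first match in `priority` wins (rarer, multi-domain-defined
# families first).
#
# The RING combination list tracks the E3-ligase subfamilies of the RING
# clan and is Pfam-release dependent; edit here rather than in code.
priority:
  - Cullin
  - APC
  - RP
  - CP
  - E1
  - HECT
  - E2
  - Skp1
  - FBX
  - RING
  - BTB
families:
  E1:
    combinations:
      - [ThiF]
      - [UBA_e1_thiolCys]
  E2:
    combinations:
      - [UQ_con]
  FBX:
    combinations:
      - [F-box]
      - [F-box-like]
  RING:
    combinations:
      - [zf-RING_2]
      - [zf-C3HC4]
      - [zf-C3HC4_2]
      - [zf-C3HC4_3]
      - [zf-RING_5]
      - [zf-RING_UBOX]
      - [RINGv]
      - [zf-rbx1]
    excluded:
      - Prok-RING_4
  BTB:
    combinations:
      - [BTB]
      - [BTB_2]
  HECT:
    combinations:
      - [HECT]
  APC:
    combinations:
      - [Apc1]
      - [Apc3]
      - [ANAPC4_WD40]
      - [Apc5]
      - [Apc8]
      - [Apc10]
  Cullin:
    combinations:
      - [Cullin, Cullin_Nedd8]
  Skp1:
    combinations:
      - [Skp1]
      - [Skp1_POZ]
  RP:
    combinations:
      - [Pro_isomerase]
      - [Prot_ATP_ID_OB]
      - [RPN1_RON2_N]
      - [RPN2_C]
      - [Rpn3_C, PCI]
      - [RPN5_C, PCI]
      - [RPN6_N, PCI]
      - [RPN7, PCI]
      - [YfdX, PCI]
      - [MitMem_reg, Peptidase_M13_N]
      - [VWA_2, UIM]
  CP:
    combinations:
      - [Proteasome]
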