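# Default candidate-descriptor set for a free arylboronic-acid library in
# the idealized toy atom layout (ring carbons 1-6 with the ipso carbon
# first, boron 7, B(OH)2 oxygens/hydrogens 8-11, ring hydrogens 12-15,
# substituent from 16). Edit atom indices to match your own structures;
# the winning descriptors of any given model are a data-driven subset of a
# list like this one.
- kind: sterimol_L
  atoms: [4, 16]
  label: L_sub
- kind: sterimol_B1
  atoms: [4, 16]
  label: B1_sub
- kind: sterimol_B5
  atoms: [4, 16]
  label: B5_sub
- kind: bond_length
  atoms: [1, 7]
  label: d_CB
- kind: bond_length
  atoms: [7, 8]
  label: d_BO
- kind: distance
  atoms: [9, 11]
  label: d_HH_OH
- kind: dihedral
  atoms: [2, 1, 7, 8]
  label: phi_ring_BO
- kind: charge
  atoms: [7]
  label: q_B
- kind: charge
  atoms: [9]
  label: q_H_O1
- kind: charge_difference
  atoms: [11, 8]
  label: dq_H2_O1
- kind: charge_difference
  atoms: [7, 1]
  label: dq_B_C
- kind: dipole_total
  label: mu_tot
- kind: dipole_component
  axis: axis1
  label: mu_ipso
- kind: dipole_component
  axis: axis2
  label: mu_ortho_meta
- kind: frequency
  mode: B-O_stretch
  label: nu_BO
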