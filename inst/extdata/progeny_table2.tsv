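cross	medium	genotype_class	count
nic1-1	R+NAM	NIC;NPT1	6
nic1-1	R+NAM	NIC;npt1	16
nic1-1	R+NAM	nic;NPT1	12
nic1-1	R+NAM	nic;npt1	0
nic2-1	R+NAM	NIC;NPT1	27
nic2-1	R+NAM	NIC;npt1	26
nic2-1	R+NAM	nic;NPT1	20
nic2-1	R+NAM	nic;npt1	0
nic13-1	R+NAM	NIC;NPT1	8
nic13-1	R+NAM	NIC;npt1	6
nic13-1	R+NAM	nic;NPT1	8
nic13-1	R+NAM	nic;npt1	0
nic15-1	R+NAM	NIC;NPT1	27
nic15-1	R+NAM	NIC;npt1	26
nic15-1	R+NAM	nic;NPT1	16
nic15-1	R+NAM	nic;npt1	0
nic1-1	R+NMN	NIC;NPT1	15
nic1-1	R+NMN	NIC;npt1	7
nic1-1	R+NMN	nic;NPT1	9
nic1-1	R+NMN	nic;npt1	0
nic2-1	R+NMN	NIC;NPT1	19
nic2-1	R+NMN	NIC;npt1	18
nic2-1	R+NMN	nic;NPT1	16
nic2-1	R+NMN	nic;npt1	0
nic13-1	R+NMN	NIC;NPT1	1
nic13-1	R+NMN	NIC;npt1	5
nic13-1	R+NMN	nic;NPT1	2
nic13-1	R+NMN	nic;npt1	0
nic15-1	R+NMN	NIC;NPT1	15
nic15-1	R+NMN	NIC;npt1	24
nic15-1	R+NMN	nic;NPT1	17
nic15-1	R+NMN	nic;npt1	0
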