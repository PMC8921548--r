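criteria	expected
	vus
PVS1	vus
PS4	vus
PVS1,PS4	pathogenic
PM1	vus
PVS1,PM1	likely_pathogenic
PS4,PM1	likely_pathogenic
PVS1,PS4,PM1	pathogenic
PM2	vus
PVS1,PM2	likely_pathogenic
PS4,PM2	likely_pathogenic
PVS1,PS4,PM2	pathogenic
PM1,PM2	vus
PVS1,PM1,PM2	pathogenic
PS4,PM1,PM2	likely_pathogenic
PVS1,PS4,PM1,PM2	pathogenic
PP1	vus
PVS1,PP1	vus
PS4,PP1	vus
PVS1,PS4,PP1	pathogenic
PM1,PP1	vus
PVS1,PM1,PP1	pathogenic
PS4,PM1,PP1	likely_pathogenic
PVS1,PS4,PM1,PP1	pathogenic
PM2,PP1	vus
PVS1,PM2,PP1	pathogenic
PS4,PM2,PP1	likely_pathogenic
PVS1,PS4,PM2,PP1	pathogenic
PM1,PM2,PP1	vus
PVS1,PM1,PM2,PP1	pathogenic
PS4,PM1,PM2,PP1	likely_pathogenic
PVS1,PS4,PM1,PM2,PP1	pathogenic
PP3	vus
PVS1,PP3	vus
PS4,PP3	vus
PVS1,PS4,PP3	pathogenic
PM1,PP3	vus
PVS1,PM1,PP3	pathogenic
PS4,PM1,PP3	likely_pathogenic
PVS1,PS4,PM1,PP3	pathogenic
PM2,PP3	vus
PVS1,PM2,PP3	pathogenic
PS4,PM2,PP3	likely_pathogenic
PVS1,PS4,PM2,PP3	pathogenic
PM1,PM2,PP3	vus
PVS1,PM1,PM2,PP3	pathogenic
PS4,PM1,PM2,PP3	likely_pathogenic
PVS1,PS4,PM1,PM2,PP3	pathogenic
PP1,PP3	vus
PVS1,PP1,PP3	pathogenic
PS4,PP1,PP3	likely_pathogenic
PVS1,PS4,PP1,PP3	pathogenic
PM1,PP1,PP3	vus
PVS1,PM1,PP1,PP3	pathogenic
PS4,PM1,PP1,PP3	likely_pathogenic
PVS1,PS4,PM1,PP1,PP3	pathogenic
PM2,PP1,PP3	vus
PVS1,PM2,PP1,PP3	pathogenic
PS4,PM2,PP1,PP3	likely_pathogenic
PVS1,PS4,PM2,PP1,PP3	pathogenic
PM1,PM2,PP1,PP3	likely_pathogenic
PVS1,PM1,PM2,PP1,PP3	pathogenic
PS4,PM1,PM2,PP1,PP3	pathogenic
PVS1,PS4,PM1,PM2,PP1,PP3	pathogenic
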