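index	class	feature	name
1	firstorder	10Percentile	firstorder_10Percentile
2	firstorder	90Percentile	firstorder_90Percentile
3	firstorder	Energy	firstorder_Energy
4	firstorder	Entropy	firstorder_Entropy
5	firstorder	InterquartileRange	firstorder_InterquartileRange
6	firstorder	Kurtosis	firstorder_Kurtosis
7	firstorder	Maximum	firstorder_Maximum
8	firstorder	Mean	firstorder_Mean
9	firstorder	MeanAbsoluteDeviation	firstorder_MeanAbsoluteDeviation
10	firstorder	Median	firstorder_Median
11	firstorder	Minimum	firstorder_Minimum
12	firstorder	Range	firstorder_Range
13	firstorder	RobustMeanAbsoluteDeviation	firstorder_RobustMeanAbsoluteDeviation
14	firstorder	RootMeanSquared	firstorder_RootMeanSquared
15	firstorder	Skewness	firstorder_Skewness
16	firstorder	TotalEnergy	firstorder_TotalEnergy
17	firstorder	Uniformity	firstorder_Uniformity
18	firstorder	Variance	firstorder_Variance
19	shape	Elongation	shape_Elongation
20	shape	Flatness	shape_Flatness
21	shape	LeastAxisLength	shape_LeastAxisLength
22	shape	MajorAxisLength	shape_MajorAxisLength
23	shape	Maximum2DDiameterColumn	shape_Maximum2DDiameterColumn
24	shape	Maximum2DDiameterRow	shape_Maximum2DDiameterRow
25	shape	Maximum2DDiameterSlice	shape_Maximum2DDiameterSlice
26	shape	Maximum3DDiameter	shape_Maximum3DDiameter
27	shape	MeshVolume	shape_MeshVolume
28	shape	MinorAxisLength	shape_MinorAxisLength
29	shape	Sphericity	shape_Sphericity
30	shape	SurfaceArea	shape_SurfaceArea
31	shape	SurfaceVolumeRatio	shape_SurfaceVolumeRatio
32	shape	VoxelVolume	shape_VoxelVolume
33	glcm	Autocorrelation	glcm_Autocorrelation
34	glcm	ClusterProminence	glcm_ClusterProminence
35	glcm	ClusterShade	glcm_ClusterShade
36	glcm	ClusterTendency	glcm_ClusterTendency
37	glcm	Contrast	glcm_Contrast
38	glcm	Correlation	glcm_Correlation
39	glcm	DifferenceAverage	glcm_DifferenceAverage
40	glcm	DifferenceEntropy	glcm_DifferenceEntropy
41	glcm	DifferenceVariance	glcm_DifferenceVariance
42	glcm	Id	glcm_Id
43	glcm	Idm	glcm_Idm
44	glcm	Idmn	glcm_Idmn
45	glcm	Idn	glcm_Idn
46	glcm	Imc1	glcm_Imc1
47	glcm	Imc2	glcm_Imc2
48	glcm	InverseVariance	glcm_InverseVariance
49	glcm	JointAverage	glcm_JointAverage
50	glcm	JointEnergy	glcm_JointEnergy
51	glcm	JointEntropy	glcm_JointEntropy
52	glcm	MaximumProbability	glcm_MaximumProbability
53	glcm	SumEntropy	glcm_SumEntropy
54	glcm	SumSquares	glcm_SumSquares
55	glrlm	GrayLevelNonUniformity	glrlm_GrayLevelNonUniformity
56	glrlm	GrayLevelNonUniformityNormalized	glrlm_GrayLevelNonUniformityNormalized
57	glrlm	GrayLevelVariance	glrlm_GrayLevelVariance
58	glrlm	HighGrayLevelRunEmphasis	glrlm_HighGrayLevelRunEmphasis
59	glrlm	LongRunEmphasis	glrlm_LongRunEmphasis
60	glrlm	LongRunHighGrayLevelEmphasis	glrlm_LongRunHighGrayLevelEmphasis
61	glrlm	LongRunLowGrayLevelEmphasis	glrlm_LongRunLowGrayLevelEmphasis
62	glrlm	LowGrayLevelRunEmphasis	glrlm_LowGrayLevelRunEmphasis
63	glrlm	RunEntropy	glrlm_RunEntropy
64	glrlm	RunLengthNonUniformity	glrlm_RunLengthNonUniformity
65	glrlm	RunLengthNonUniformityNormalized	glrlm_RunLengthNonUniformityNormalized
66	glrlm	RunPercentage	glrlm_RunPercentage
67	glrlm	RunVariance	glrlm_RunVariance
68	glrlm	ShortRunEmphasis	glrlm_ShortRunEmphasis
69	glrlm	ShortRunHighGrayLevelEmphasis	glrlm_ShortRunHighGrayLevelEmphasis
70	glrlm	ShortRunLowGrayLevelEmphasis	glrlm_ShortRunLowGrayLevelEmphasis
71	glszm	GrayLevelNonUniformity	glszm_GrayLevelNonUniformity
72	glszm	GrayLevelNonUniformityNormalized	glszm_GrayLevelNonUniformityNormalized
73	glszm	GrayLevelVariance	glszm_GrayLevelVariance
74	glszm	HighGrayLevelZoneEmphasis	glszm_HighGrayLevelZoneEmphasis
75	glszm	LargeAreaEmphasis	glszm_LargeAreaEmphasis
76	glszm	LargeAreaHighGrayLevelEmphasis	glszm_LargeAreaHighGrayLevelEmphasis
77	glszm	LargeAreaLowGrayLevelEmphasis	glszm_LargeAreaLowGrayLevelEmphasis
78	glszm	LowGrayLevelZoneEmphasis	glszm_LowGrayLevelZoneEmphasis
79	glszm	SizeZoneNonUniformity	glszm_SizeZoneNonUniformity
80	glszm	SizeZoneNonUniformityNormalized	glszm_SizeZoneNonUniformityNormalized
81	glszm	SmallAreaEmphasis	glszm_SmallAreaEmphasis
82	glszm	SmallAreaHighGrayLevelEmphasis	glszm_SmallAreaHighGrayLevelEmphasis
83	glszm	SmallAreaLowGrayLevelEmphasis	glszm_SmallAreaLowGrayLevelEmphasis
84	glszm	ZoneEntropy	glszm_ZoneEntropy
85	glszm	ZonePercentage	glszm_ZonePercentage
86	glszm	ZoneVariance	glszm_ZoneVariance
87	gldm	DependenceEntropy	gldm_DependenceEntropy
88	gldm	DependenceNonUniformity	gldm_DependenceNonUniformity
89	gldm	DependenceNonUniformityNormalized	gldm_DependenceNonUniformityNormalized
90	gldm	DependenceVariance	gldm_DependenceVariance
91	gldm	GrayLevelNonUniformity	gldm_GrayLevelNonUniformity
92	gldm	GrayLevelVariance	gldm_GrayLevelVariance
93	gldm	HighGrayLevelEmphasis	gldm_HighGrayLevelEmphasis
94	gldm	LargeDependenceEmphasis	gldm_LargeDependenceEmphasis
95	gldm	LargeDependenceHighGrayLevelEmphasis	gldm_LargeDependenceHighGrayLevelEmphasis
96	gldm	LargeDependenceLowGrayLevelEmphasis	gldm_LargeDependenceLowGrayLevelEmphasis
97	gldm	LowGrayLevelEmphasis	gldm_LowGrayLevelEmphasis
98	gldm	SmallDependenceEmphasis	gldm_SmallDependenceEmphasis
99	gldm	SmallDependenceHighGrayLevelEmphasis	gldm_SmallDependenceHighGrayLevelEmphasis
100	gldm	SmallDependenceLowGrayLevelEmphasis	gldm_SmallDependenceLowGrayLevelEmphasis
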