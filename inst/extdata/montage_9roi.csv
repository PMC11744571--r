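channel,roi,roi_label
C10,1,medial_frontal
C12,1,medial_frontal
C14,1,medial_frontal
C2,2,left_superior_frontal
C7,2,left_superior_frontal
C8,2,left_superior_frontal
C9,2,left_superior_frontal
C13,2,left_superior_frontal
C37,2,left_superior_frontal
C39,2,left_superior_frontal
C40,2,left_superior_frontal
C1,3,left_middle_frontal
C3,3,left_middle_frontal
C4,3,left_middle_frontal
C5,3,left_middle_frontal
C6,3,left_middle_frontal
C38,4,left_precentral
C47,4,left_precentral
C48,4,left_precentral
C41,5,left_parietal
C42,5,left_parietal
C43,5,left_parietal
C44,5,left_parietal
C45,5,left_parietal
C46,5,left_parietal
C49,5,left_parietal
C11,6,right_superior_frontal
C15,6,right_superior_frontal
C16,6,right_superior_frontal
C17,6,right_superior_frontal
C19,6,right_superior_frontal
C31,6,right_superior_frontal
C32,6,right_superior_frontal
C34,6,right_superior_frontal
C18,7,right_middle_frontal
C20,7,right_middle_frontal
C21,7,right_middle_frontal
C22,7,right_middle_frontal
C23,7,right_middle_frontal
C24,8,right_precentral
C26,8,right_precentral
C33,8,right_precentral
C25,9,right_parietal
C27,9,right_parietal
C28,9,right_parietal
C29,9,right_parietal
C30,9,right_parietal
C35,9,right_parietal
C36,9,right_parietal
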